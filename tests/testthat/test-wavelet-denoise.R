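test_that("the improved threshold function obeys its defining limits", {
  T <- 0.8
  x <- seq(-10, 10, by = 0.01)
  f <- improved_threshold(x, T)
  # dead zone, continuity at |x| = T
  expect_true(all(f[abs(x) < T] == 0))
  expect_equal(improved_threshold(T, T), 0)
  expect_equal(improved_threshold(-T, T), 0)
  # odd and shrinking
  expect_equal(f, -rev(f))
  expect_true(all(abs(f) <= abs(x) + 1e-12))
  # soft limit: f(x) - (x - T) -> 0 as x -> T+
  for (eps in c(1e-3, 1e-6))
    expect_lt(abs(improved_threshold(T + eps, T) - eps), eps)
  # hard-threshold asymptote: f(10T) within 1e-3 T of 10T - 2T/(e^9 + 1)
  expect_lt(abs(improved_threshold(10 * T, T) -
                  (10 * T - 2 * T / (exp(9) + 1))), 1e-3 * T)
  expect_gt(improved_threshold(1000 * T, T) / (1000 * T), 1 - 1e-6)
  # T = 0 degenerates to the identity
  expect_equal(improved_threshold(x, 0), x)
  expect_error(improved_threshold(1, -1))
})

test_that("the sym8 pyramid reconstructs exactly", {
  ecgfusion:::with_seed(3, {
    x <- rnorm(1024)
    dec <- ecgfusion:::wavelet_decompose(x, 5)
    expect_equal(length(dec$details), 5L)
    expect_lt(max(abs(ecgfusion:::wavelet_reconstruct(dec) - x)), 1e-10)
  })
})

test_that("wavelet denoising shrinks noise but passes smooth structure", {
  expect_equal(wavelet_denoise_component(numeric(256)), numeric(256))
  ecgfusion:::with_seed(17, {
    noise <- rnorm(2048)
    den <- wavelet_denoise_component(noise)
    expect_lt(sum(den^2), 0.2 * sum(noise^2))
  })
  t_ax <- seq(0, 1, length.out = 1024)
  smooth <- sin(2 * pi * 3 * t_ax)
  den <- wavelet_denoise_component(smooth)
  expect_equal(length(den), 1024L)
  expect_gt(denoise_metrics(smooth, den)$ncc, 0.99)
  # non-dyadic lengths are padded and trimmed back
  odd <- sin(2 * pi * 3 * seq(0, 1, length.out = 1000))
  expect_equal(length(wavelet_denoise_component(odd)), 1000L)
  expect_error(wavelet_denoise_component(numeric(16), threshold_params(levels = 5)),
               "shorter")
})

test_that("denoise metrics match their closed forms", {
  t_ax <- (0:999) / 1000        # complete periods: exact orthogonality
  clean <- sin(2 * pi * 5 * t_ax)
  m <- denoise_metrics(clean, clean)
  expect_equal(m$snr_db, Inf)
  expect_equal(m$rmse, 0)
  expect_equal(m$ncc, 1)
  expect_equal(denoise_metrics(clean, 2 * clean)$ncc, 1)
  # orthogonal contamination at 1/10 amplitude: SNR = 20 dB exactly
  noisy <- clean + 0.1 * cos(2 * pi * 5 * t_ax)
  expect_equal(denoise_metrics(clean, noisy)$snr_db, 20, tolerance = 1e-6)
  expect_error(denoise_metrics(numeric(10), numeric(10)), "zero energy")
})

test_that("the 1.5 Hz rule removes baseline wander", {
  rec <- fixture_record(duration_s = 6, seed = 31)
  clean <- rec$signal[, 1]
  noisy <- add_noise(rec, noise_spec(baseline_amp = 0.3,
                                     baseline_freq_hz = 0.5,
                                     seed = 7))$signal[, 1]
  den <- denoise_record(noisy, fast_iceemdan(), fs = rec$fs)
  rms_in <- sqrt(mean((noisy - clean)^2))
  rms_out <- sqrt(mean((as.numeric(den) - clean)^2))
  expect_lt(rms_out, rms_in / 5)
})

test_that("denoising a clean record is near-identity", {
  clean <- fixture_record(duration_s = 6, seed = 32)$signal[, 1]
  den <- denoise_record(clean, fast_iceemdan(), fs = 360)
  expect_gt(denoise_metrics(clean, as.numeric(den))$ncc, 0.99)
})

test_that("denoising improves the SNR of a noisy record", {
  rec <- fixture_record(duration_s = 6, seed = 33)
  clean <- rec$signal[, 1]
  noisy <- add_noise(rec, noise_spec(gaussian_snr_db = 5, seed = 9))$signal[, 1]
  den <- denoise_record(noisy, fast_iceemdan(), fs = rec$fs)
  m <- denoise_metrics(clean, as.numeric(den), noisy)
  expect_gt(m$snr_db, m$input_snr_db)
  expect_error(denoise_record(numeric(100)), "512")
})
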