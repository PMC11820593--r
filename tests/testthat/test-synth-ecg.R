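test_that("clean records have the forced length, beat count and labels", {
  rec <- generate_clean_record(synth_config(duration_s = 10,
                                            class_mix = c(N = 1),
                                            beat_rate_bpm = 72, seed = 1))
  expect_equal(nrow(rec$signal), 3600L)          # 360 Hz x 10 s
  expect_equal(nrow(rec$annotations), 12L)       # 72 bpm x 10 s
  expect_true(all(rec$annotations$symbol == "N"))

  rec5 <- generate_clean_record(synth_config(duration_s = 5, seed = 1))
  expect_equal(nrow(rec5$signal), 1800L)         # the 5-s slice length
})

test_that("generation is bit-reproducible and annotations are well-formed", {
  for (seed in c(1, 7, 23)) {
    cfg <- synth_config(duration_s = 15,
                        class_mix = c(N = 0.5, S = 0.2, V = 0.2, Q = 0.1),
                        seed = seed)
    a <- generate_clean_record(cfg)
    b <- generate_clean_record(cfg)
    expect_identical(a$signal, b$signal)
    expect_identical(a$annotations, b$annotations)
    idx <- a$annotations$sample
    expect_true(all(diff(idx) > 0))
    expect_true(all(idx >= 0 & idx < nrow(a$signal)))
  }
})

test_that("invalid generator configurations are rejected", {
  expect_error(synth_config(class_mix = c(N = 0.5, V = 0.4)), "sum to 1")
  expect_error(synth_config(class_mix = c(X = 1)), "AAMI")
  expect_error(
    generate_clean_record(synth_config(duration_s = 0.5, beat_rate_bpm = 40)),
    "shorter than one beat")
})

test_that("beat classes have distinct morphologies", {
  mk <- function(cl) {
    generate_clean_record(synth_config(duration_s = 5,
                                       class_mix = stats::setNames(1, cl),
                                       seed = 4))$signal[, 1]
  }
  n <- mk("N"); v <- mk("V"); q <- mk("Q")
  expect_gt(max(v), max(n))            # V beats are larger
  expect_lt(max(q), 0.7 * max(n))      # Q beats are low-amplitude
})

test_that("zero noise is the identity and the realized Gaussian SNR is exact", {
  rec <- fixture_record(duration_s = 10)
  quiet <- add_noise(rec, noise_spec(baseline_amp = 0, gaussian_snr_db = Inf,
                                     powerline_amp = 0))
  expect_equal(quiet$signal, rec$signal)
  expect_identical(quiet$annotations, rec$annotations)

  noisy <- add_noise(rec, noise_spec(gaussian_snr_db = 10, seed = 2))
  g <- attr(noisy, "noise_components")[[1]]$gaussian
  snr <- 10 * log10(mean(rec$signal[, 1]^2) / mean(g^2))
  expect_lt(abs(snr - 10), 0.1)
  expect_identical(noisy$annotations, rec$annotations)
})

test_that("the baseline component is a sinusoid at the requested frequency", {
  rec <- fixture_record(duration_s = 20)
  spec <- noise_spec(baseline_amp = 0.4, baseline_freq_hz = 0.5, seed = 5)
  noisy <- add_noise(rec, spec)
  comps <- attr(noisy, "noise_components")[[1]]
  baseline <- noisy$signal[, 1] - rec$signal[, 1] -
    comps$gaussian - comps$powerline
  n <- length(baseline)
  mag <- Mod(stats::fft(baseline))[2:(n %/% 2)]
  peak_hz <- which.max(mag) * rec$fs / n
  expect_equal(peak_hz, 0.5, tolerance = 0.05)
  expect_lt(max(abs(baseline)), 0.4 + 1e-9)
})
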