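test_that("PAA compression averages equal frames", {
  expect_equal(paa_compress(rep(3.5, 1800), 100), rep(3.5, 100))
  expect_length(paa_compress(rnorm(1800), 100), 100L)
  ramp <- paa_compress(0:1799, 100)
  expect_equal(ramp[1:3], c(8.5, 26.5, 44.5))   # means of 18-sample frames
  # non-divisible length: last frame padded by repeating the final sample
  expect_length(paa_compress(1:1795, 100), 100L)
  expect_error(paa_compress(1:50, 100), "shorter")
})

test_that("GADF matches the polar-angle construction", {
  # series rescaling to (1, 0, -1): angles 0, 90, 180 degrees
  G <- gadf(c(1, 0.5, 0))
  expect_equal(G[1, 2], -1)
  expect_equal(G[2, 1], 1)
  expect_equal(diag(G), rep(0, 3))
  expect_error(gadf(rep(2, 10)), "constant")
})

test_that("GADF is antisymmetric with zero diagonal on random series", {
  ecgfusion:::with_seed(1, {
    for (trial in 1:100) {
      x <- rnorm(20)
      G <- gadf(x)
      expect_equal(diag(G), rep(0, 20))
      expect_lt(max(abs(G + t(G))), 1e-12)
      expect_true(all(G >= -1 - 1e-12 & G <= 1 + 1e-12))
    }
  })
})

test_that("MTF transition probabilities match a hand count", {
  r <- mtf(c(1, 1, 2, 2), Q = 2)
  expect_equal(r$W, matrix(c(0.5, 0, 0.5, 1), 2))
  expect_equal(r$mtf[1, 4], 0.5)
  expect_equal(dim(r$mtf), c(4L, 4L))
  # a single repeated state collapses to probability 1 everywhere
  expect_true(all(mtf(rep(2, 6), Q = 4)$mtf == 1))
  expect_error(mtf(1, Q = 2), "length")
})

test_that("MTF rows are stochastic and entries are probabilities", {
  ecgfusion:::with_seed(2, {
    for (trial in 1:100) {
      r <- mtf(rnorm(40), Q = 8)
      expect_equal(unname(rowSums(r$W)), rep(1, nrow(r$W)))
      expect_true(all(r$mtf >= 0 & r$mtf <= 1))
    }
  })
})

test_that("recurrence plots threshold pairwise distances", {
  expect_equal(rp(c(0, 100), epsilon = 30), matrix(c(1L, 0L, 0L, 1L), 2))
  expect_true(all(rp(rep(1, 5)) == 1))
  # delay embedding shrinks the plot: n - (m-1) tau points
  expect_equal(dim(rp(rnorm(20), epsilon = 1, m = 3, tau = 2)), c(16L, 16L))
  expect_error(rp(c(1, 2), epsilon = 1, m = 3, tau = 2), "fewer than 2")
})

test_that("recurrence plots are symmetric binary with unit diagonal", {
  ecgfusion:::with_seed(4, {
    for (trial in 1:100) {
      R <- rp(rnorm(25, sd = 40), epsilon = 30)
      expect_identical(R, t(R))
      expect_equal(diag(R), rep(1L, 25))
      expect_true(all(R %in% c(0L, 1L)))
    }
  })
})

test_that("channel stacking maps value ranges to 8-bit half-up", {
  G <- matrix(0, 2, 2); M <- matrix(0.5, 2, 2); R <- matrix(1, 2, 2)
  img <- stack_rgb(G, M, R)
  expect_equal(img[1, 1, 1], 128L)   # GADF 0 -> round(127.5) half-up
  expect_equal(img[1, 1, 2], 128L)
  expect_equal(img[1, 1, 3], 255L)
  expect_error(stack_rgb(G, M, matrix(1, 3, 3)), "mismatch")
})

test_that("segment encoding yields a 100x100x3 image under both modes", {
  seg <- fixture_record(duration_s = 5)$signal[, 1] * 200
  tr <- encode_segment(seg, imaging_config())
  expect_equal(dim(tr$rgb), c(100L, 100L, 3L))
  expect_equal(dim(tr$gadf), c(100L, 100L))
  expect_true(all(tr$rgb >= 0 & tr$rgb <= 255))
  tr2 <- encode_segment(seg, imaging_config(compression = "resize"))
  expect_equal(dim(tr2$rgb), c(100L, 100L, 3L))
  # the recurrence channel reacts to the epsilon threshold
  few <- encode_segment(seg, imaging_config(rp_epsilon = 1))
  expect_lt(sum(few$rp), sum(tr$rp))
})
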