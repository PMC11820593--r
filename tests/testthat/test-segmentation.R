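test_that("window starts follow the stride arithmetic", {
  rec <- ecg_record(matrix(rnorm(3600), ncol = 1), fs = 360,
                    annotations = data.frame(sample = c(100L, 1800L),
                                             symbol = c("N", "V")))
  sl <- slice_record(rec, slice_config())
  expect_length(sl, 3L)
  expect_equal(vapply(sl, `[[`, 0L, "start"), c(0L, 900L, 1800L))
  expect_true(all(vapply(sl, function(s) length(s$samples), 0L) == 1800L))
  # half-open interval: the beat at 1800 is NOT in window [0, 1800)
  expect_equal(sl[[1]]$beat_labels, "N")
  expect_true("V" %in% sl[[2]]$beat_labels)   # [900, 2700) contains 1800
  expect_equal(sl[[3]]$beat_labels, "V")

  one <- slice_record(ecg_record(matrix(0, 1800, 1), 360), slice_config())
  expect_length(one, 1L)
  expect_error(slice_record(ecg_record(matrix(0, 100, 1), 360),
                            slice_config()), "shorter")
})

test_that("slice labeling follows the four rules", {
  expect_equal(label_slice(c("N", "N", "N", "N")), "N")        # rule 1
  expect_equal(label_slice(c("N", "N", "V")), "V")             # rule 2
  expect_equal(label_slice(c("N", "S", "S", "V")), "S")        # rule 3
  expect_equal(label_slice(c("V", "N", "S")), "V")             # rule 4 (tie)
  expect_equal(label_slice(c("S", "N", "V")), "S")
  expect_error(label_slice(character(0)), "no beats")
})

test_that("labeling is permutation-invariant except on rule-4 ties", {
  ecgfusion:::with_seed(5, {
    for (trial in 1:50) {
      labs <- sample(c("N", "S", "V", "F", "Q"), 8, replace = TRUE,
                     prob = c(0.5, 0.2, 0.15, 0.1, 0.05))
      abn <- labs[labs != "N"]
      counts <- table(abn)
      tie <- length(abn) > 0 && sum(counts == max(counts)) > 1
      l1 <- label_slice(labs)
      l2 <- label_slice(sample(labs))
      if (!tie) expect_identical(l1, l2)
      # under a tie the result is still one of the tied types
      if (tie) expect_true(l2 %in% names(counts)[counts == max(counts)])
    }
  })
})

test_that("make_segments yields 1800-point labeled slices", {
  ss <- make_segments(fixture_record(duration_s = 20))
  expect_s3_class(ss, "segment_set")
  expect_equal(ncol(ss$segments), 1800L)
  expect_true(all(as.character(ss$labels) %in% aami_levels()))
})

test_that("partition holds out the test split before balancing, no leakage", {
  ecgfusion:::with_seed(9, {
    n <- 100
    segs <- matrix(rnorm(n * 24), n)
    labs <- rep(c("N", "S", "V", "F", "Q"), each = 20)
    ss <- segment_set(segs, labs)
    parts <- partition_segments(ss, seed = 3,
                                smote_cfg = smote_config(k_neighbors = 3,
                                                         seed = 3))
    expect_equal(nrow(parts$test$segments), 20L)      # 20% held out
    expect_equal(as.integer(table(parts$test$labels)), rep(4L, 5))
    # no held-out row participates anywhere in the balanced data
    pool <- rbind(parts$train$segments, parts$val$segments)
    key <- function(m) apply(round(m, 10), 1, paste, collapse = ",")
    expect_length(intersect(key(parts$test$segments), key(pool)), 0L)
    # fractional validation sample rounds toward validation
    n_bal <- nrow(pool)
    expect_equal(nrow(parts$val$segments), as.integer(ceiling(0.3 * n_bal)))
    # determinism
    parts2 <- partition_segments(ss, seed = 3,
                                 smote_cfg = smote_config(k_neighbors = 3,
                                                          seed = 3))
    expect_identical(parts$train$segments, parts2$train$segments)
    expect_identical(parts$test$segments, parts2$test$segments)
  })
  tiny <- segment_set(matrix(rnorm(3 * 8), 3), c("N", "N", "V"))
  expect_error(partition_segments(tiny, seed = 1, smote_cfg = NULL),
               "< 2 members")
})
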