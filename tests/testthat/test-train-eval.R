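test_that("evaluation metrics match hand-computed one-vs-rest counts", {
  # class V: TP = 9, FN = 1, FP = 2, TN = 8 in a 20-sample problem
  truth <- c(rep("V", 10), rep("N", 10))
  pred <- c(rep("V", 9), "N", rep("V", 2), rep("N", 8))
  rep_ <- evaluate_predictions(truth, pred)
  v <- rep_$per_class$V
  expect_equal(v$sen, 0.9)
  expect_equal(v$ppv, 9 / 11)
  expect_equal(v$spec, 0.8)
  expect_equal(v$acc, 0.85)
  expect_equal(v$f1, 2 * (9 / 11) * 0.9 / (9 / 11 + 0.9))
  expect_equal(v$f1, 0.857142857, tolerance = 1e-6)
  # confusion matrix row sums equal true class counts; OA = trace/total
  expect_equal(unname(rowSums(rep_$confusion)[c("N", "V")]), c(10, 10))
  expect_equal(rep_$oa, sum(diag(rep_$confusion)) / 20)
})

test_that("perfect predictions score 1 on every metric", {
  labs <- rep(aami_levels(), times = c(5, 4, 3, 2, 2))
  rep_ <- evaluate_predictions(labs, labs)
  expect_equal(rep_$oa, 1)
  for (cl in aami_levels()) {
    expect_equal(rep_$per_class[[cl]]$ppv, 1)
    expect_equal(rep_$per_class[[cl]]$sen, 1)
    expect_equal(rep_$per_class[[cl]]$spec, 1)
    expect_equal(rep_$per_class[[cl]]$f1, 1)
    expect_equal(rep_$per_class[[cl]]$acc, 1)
  }
})

test_that("F1 is the harmonic mean, bounded by PPV and Sen", {
  ecgfusion:::with_seed(12, {
    for (trial in 1:20) {
      truth <- sample(aami_levels(), 60, replace = TRUE)
      pred <- sample(aami_levels(), 60, replace = TRUE)
      rep_ <- evaluate_predictions(truth, pred)
      for (cl in aami_levels()) {
        p <- rep_$per_class[[cl]]
        if (is.na(p$sen) || p$ppv + p$sen == 0) next
        expect_gte(p$f1 + 1e-12, min(p$ppv, p$sen))
        expect_lte(p$f1 - 1e-12, max(p$ppv, p$sen))
      }
      expect_equal(sum(rep_$confusion), 60)
    }
  })
})

test_that("a never-predicted class reports PPV 0 with a flag", {
  truth <- c("N", "N", "V", "V")
  pred <- c("N", "N", "N", "N")
  rep_ <- evaluate_predictions(truth, pred)
  expect_equal(rep_$per_class$V$ppv, 0)
  expect_true(rep_$per_class$V$ppv_undefined)
  expect_false(rep_$per_class$N$ppv_undefined)
})

test_that("training separates two linearly separable classes", {
  cfg <- tiny_net_cfg(dropout = 0)
  dat <- tiny_two_class_data(n_per_class = 10, cfg = cfg)
  expect_warning(
    fit <- fit_fusion(dat$segments, dat$images, dat$labels,
                      model = fusion_model(cfg, seed = 2),
                      cfg = train_config(lr = 0.003, batch_size = 20L,
                                         epochs = 20L, seed = 2)),
    "absent")
  expect_gt(utils::tail(fit$history$train_acc, 1), 0.95)
  # loss trends downward over training (Spearman)
  rho <- stats::cor(fit$history$epoch, fit$history$loss, method = "spearman")
  expect_lt(rho, 0)
  # prediction interface round-trips
  pred <- predict(fit, dat$segments, dat$images)
  expect_s3_class(pred, "factor")
  expect_gt(mean(as.character(pred) == dat$labels), 0.95)
  probs <- predict(fit, dat$segments, dat$images, type = "prob")
  expect_equal(rowSums(probs), rep(1, 20), tolerance = 1e-6)
  rep_ <- evaluate_model(fit, dat$segments, dat$images, dat$labels)
  expect_s3_class(rep_, "eval_report")
  expect_gt(rep_$oa, 0.95)
})

test_that("a scaled-down network memorizes one batch", {
  cfg <- tiny_net_cfg(dropout = 0)
  ecgfusion:::with_seed(44, {
    n <- 16
    segs <- matrix(rnorm(n * cfg$input_len), n)
    imgs <- array(runif(n * cfg$image_size^2 * 3) * 255,
                  c(n, cfg$image_size, cfg$image_size, 3))
    labs <- sample(aami_levels(), n, replace = TRUE)
    fit <- suppressWarnings(
      fit_fusion(segs, imgs, labs, model = fusion_model(cfg, seed = 3),
                 cfg = train_config(lr = 0.005, batch_size = 16L,
                                    epochs = 300L, stop_loss = 0.01,
                                    seed = 3)))
    expect_lt(utils::tail(fit$history$loss, 1), 0.01)
  })
})

test_that("training is deterministic given the seed", {
  cfg <- tiny_net_cfg(dropout = 0.3)
  dat <- tiny_two_class_data(n_per_class = 4, cfg = cfg)
  run <- function() suppressWarnings(
    fit_fusion(dat$segments, dat$images, dat$labels,
               model = fusion_model(cfg, seed = 5),
               cfg = train_config(lr = 0.002, batch_size = 4L,
                                  epochs = 3L, seed = 5)))
  expect_identical(run()$history, run()$history)
})

test_that("evaluation reports serialize to JSON and CSV", {
  dir <- withr::local_tempdir()
  rep_ <- evaluate_predictions(rep(aami_levels(), 4),
                               rep(aami_levels(), 4))
  write_eval_report(rep_, file.path(dir, "r.json"), file.path(dir, "c.csv"))
  j <- jsonlite::read_json(file.path(dir, "r.json"))
  expect_equal(j$oa, 1)
  expect_equal(j$n, 20)
  cm <- utils::read.csv(file.path(dir, "c.csv"), row.names = 1)
  expect_equal(sum(as.matrix(cm)), 20)
})
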