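test_that("SMOTE fills every minority class to the majority count", {
  ecgfusion:::with_seed(2, {
    counts <- c(N = 30, S = 12, V = 9, F = 8, Q = 7)
    segs <- matrix(rnorm(sum(counts) * 16), sum(counts))
    ss <- segment_set(segs, rep(names(counts), counts))
    out <- smote_oversample(ss, smote_config(seed = 4))
    expect_equal(as.integer(table(out$labels)), rep(30L, 5))
    # originals are retained bit-identically, in order
    expect_identical(out$segments[seq_len(nrow(segs)), ], segs)
    expect_identical(as.character(out$labels[seq_len(nrow(segs))]),
                     as.character(ss$labels))
    # provenance flag marks exactly the synthetic rows
    expect_equal(sum(out$synthetic), 150L - sum(counts))
    expect_false(any(out$synthetic[seq_len(nrow(segs))]))
  })
})

test_that("a class already at target and explicit targets are honored", {
  ecgfusion:::with_seed(6, {
    ss <- segment_set(matrix(rnorm(40 * 8), 40), rep(c("N", "V"), c(25, 15)))
    out <- smote_oversample(ss, smote_config(seed = 1))
    expect_identical(out$segments[which(ss$labels == "N"), ],
                     ss$segments[which(ss$labels == "N"), ])
    out2 <- smote_oversample(ss, smote_config(target_count = 30, seed = 1))
    expect_equal(as.integer(table(droplevels(out2$labels))), c(30L, 30L))
  })
})

test_that("synthetic points are convex combinations of same-class neighbors", {
  # dimension 2 so between-ness can be verified against all pairs
  ecgfusion:::with_seed(13, {
    X <- matrix(rnorm(12 * 2), 12)
    ss <- segment_set(rbind(X, matrix(rnorm(40), 20)),
                      rep(c("V", "N"), c(12, 20)))
    out <- smote_oversample(ss, smote_config(k_neighbors = 3, seed = 5))
    synth <- out$segments[out$synthetic & out$labels == "V", , drop = FALSE]
    expect_gt(nrow(synth), 0)
    on_some_segment <- function(p) {
      for (i in 1:(nrow(X) - 1)) for (j in (i + 1):nrow(X)) {
        d <- X[j, ] - X[i, ]
        v <- p - X[i, ]
        u <- sum(v * d) / sum(d * d)
        if (u >= -1e-9 && u <= 1 + 1e-9 &&
            sqrt(sum((v - u * d)^2)) < 1e-9) return(TRUE)
      }
      FALSE
    }
    for (r in seq_len(nrow(synth)))
      expect_true(on_some_segment(synth[r, ]))
  })
})

test_that("SMOTE is deterministic and rejects undersized classes", {
  ss <- segment_set(matrix(rnorm(30 * 8), 30), rep(c("N", "V"), c(24, 6)))
  a <- smote_oversample(ss, smote_config(k_neighbors = 3, seed = 7))
  b <- smote_oversample(ss, smote_config(k_neighbors = 3, seed = 7))
  expect_identical(a$segments, b$segments)
  tiny <- segment_set(matrix(rnorm(28 * 8), 28), rep(c("N", "V"), c(24, 4)))
  expect_error(smote_oversample(tiny, smote_config(k_neighbors = 5)),
               "k_neighbors")
})

test_that("blocked nearest-neighbor search matches a direct computation", {
  ecgfusion:::with_seed(30, {
    X <- matrix(rnorm(50 * 6), 50)
    nn <- ecgfusion:::knn_indices(X, 4, block = 16L)
    D <- as.matrix(stats::dist(X))
    diag(D) <- Inf
    for (i in c(1, 17, 50))
      expect_equal(sort(nn[i, ]), sort(order(D[i, ])[1:4]))
  })
})
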