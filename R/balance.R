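#' SMOTE configuration
#'
#' @param k_neighbors Number of same-class nearest neighbors considered
#'   when interpolating; must be smaller than every minority class.
#'   Default 5 (canonical SMOTE).
#' @param target_count `"majority"` (fill every class to the largest class
#'   count) or an explicit integer.
#' @param seed Integer seed.
#' @return Object of class `smote_config`.
#' @export
smote_config <- function(k_neighbors = 5L, target_count = "majority",
                         seed = 1L) {
  if (k_neighbors < 1L) stop("k_neighbors must be positive")
  if (!(identical(target_count, "majority") ||
        (is.numeric(target_count) && target_count >= 1)))
    stop("target_count must be \"majority\" or a positive integer")
  structure(list(k_neighbors = as.integer(k_neighbors),
                 target_count = target_count, seed = as.integer(seed)),
            class = "smote_config")
}

# k nearest same-class neighbors by Euclidean distance, computed blockwise
# with the Gram-matrix identity so large classes stay within memory.
knn_indices <- function(X, k, block = 1024L) {
  n <- nrow(X)
  sq <- rowSums(X^2)
  out <- matrix(0L, n, k)
  for (lo in seq(1L, n, by = block)) {
    hi <- min(lo + block - 1L, n)
    G <- X[lo:hi, , drop = FALSE] %*% t(X)
    D2 <- sweep(-2 * G, 2, sq, `+`) + sq[lo:hi]
    for (r in seq_len(hi - lo + 1L)) {
      d <- D2[r, ]
      d[lo + r - 1L] <- Inf                 # exclude self
      out[lo + r - 1L, ] <- order(d)[seq_len(k)]
    }
  }
  out
}

#' SMOTE oversampling to balance class counts
#'
#' Each minority class is filled to the target count with synthetic points
#' `x_new = x_i + u * (x_nn - x_i)`, `u ~ Uniform(0, 1)`, where `x_nn` is
#' one of the `k` nearest same-class neighbors of `x_i` under the
#' Euclidean metric on the raw segment vectors. Original rows are kept
#' bit-identical; synthetic rows are flagged in the returned set's
#' `synthetic` field so evaluation can exclude them.
#'
#' @param segset A [segment_set()].
#' @param cfg A [smote_config()].
#' @return A `segment_set` whose class counts all equal the target.
#' @export
#' @examples
#' ss <- segment_set(matrix(rnorm(40 * 8), 40),
#'                   rep(c("N", "V"), c(30, 10)))
#' table(smote_oversample(ss, smote_config(k_neighbors = 3))$labels)
smote_oversample <- function(segset, cfg = smote_config()) {
  stopifnot(inherits(segset, "segment_set"), inherits(cfg, "smote_config"))
  counts <- table(droplevels(segset$labels))
  target <- if (identical(cfg$target_count, "majority")) max(counts)
            else as.integer(cfg$target_count)
  new_rows <- list(); new_labels <- character(0)
  for (cl in names(counts)) {
    n_cl <- counts[[cl]]
    need <- target - n_cl
    if (need <= 0) next
    if (n_cl <= cfg$k_neighbors)
      stop("class ", cl, " has ", n_cl, " members; needs > k_neighbors (",
           cfg$k_neighbors, ") for SMOTE")
    X <- segset$segments[segset$labels == cl, , drop = FALSE]
    nn <- knn_indices(X, cfg$k_neighbors)
    synth <- with_seed(derive_seed(cfg$seed, paste0("smote-", cl)), {
      parents <- sample.int(n_cl, need, replace = TRUE)
      picks <- sample.int(cfg$k_neighbors, need, replace = TRUE)
      u <- stats::runif(need)
      P <- X[parents, , drop = FALSE]
      Q <- X[nn[cbind(parents, picks)], , drop = FALSE]
      P + u * (Q - P)
    })
    new_rows[[cl]] <- synth
    new_labels <- c(new_labels, rep(cl, need))
  }
  if (!length(new_rows)) return(segset)
  segment_set(rbind(segset$segments, do.call(rbind, new_rows)),
              c(as.character(segset$labels), new_labels),
              synthetic = c(segset$synthetic, rep(TRUE, length(new_labels))))
}
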