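#' ICEEMDAN configuration
#'
#' Parameters of the improved complete ensemble empirical mode
#' decomposition with adaptive noise. An ensemble of white-noise
#' realizations is decomposed once by EMD; at stage *k* the *k*-th noise
#' mode, scaled by `noise_std_ratio * sd(signal)`, perturbs the running
#' residual before local-mean averaging, which suppresses mode mixing while
#' keeping the telescoping reconstruction exact.
#'
#' @param ensemble_size Number of white-noise realizations (>= 2).
#'   Default 50.
#' @param noise_std_ratio Noise amplitude as a fraction of the signal's
#'   standard deviation, in (0, 1). Default 0.2, held constant across
#'   stages.
#' @param max_imfs Maximum number of modes to extract. Default 12.
#' @param sift_stop_sd Sifting stop tolerance passed to the EMD engine.
#' @param seed Master seed; per-realization seeds are derived from it.
#' @return Object of class `iceemdan_config`.
#' @export
iceemdan_config <- function(ensemble_size = 50L, noise_std_ratio = 0.2,
                            max_imfs = 12L, sift_stop_sd = 0.2, seed = 1L) {
  if (ensemble_size < 2L) stop("ensemble_size must be >= 2")
  if (noise_std_ratio <= 0 || noise_std_ratio >= 1)
    stop("noise_std_ratio must lie in (0, 1)")
  structure(list(ensemble_size = as.integer(ensemble_size),
                 noise_std_ratio = noise_std_ratio,
                 max_imfs = as.integer(max_imfs),
                 sift_stop_sd = sift_stop_sd, seed = as.integer(seed)),
            class = "iceemdan_config")
}

# local mean operator M(y): y minus its first EMD mode; y itself when no
# mode can be sifted (fewer than 2 extrema per side)
local_mean <- function(y, sift_stop_sd = 0.2) {
  imf <- sift_imf(y, sift_stop_sd)
  if (is.null(imf)) y else y - imf
}

#' ICEEMDAN decomposition
#'
#' Noise-assisted EMD: stage-`k` residuals are the ensemble average of the
#' local means of the previous residual perturbed by the `k`-th EMD mode of
#' each white-noise realization; modes are the successive residual
#' differences, so `rowSums(imfs) + residual` reproduces the input exactly
#' (telescoping identity). Stops when the residual has fewer than 3 extrema
#' or `max_imfs` is reached.
#'
#' @param signal Numeric vector (length >= 8 with >= 2 extrema for a
#'   non-trivial decomposition).
#' @param cfg An [iceemdan_config()].
#' @return An [imf_set()] with per-mode dominant frequencies when `fs` is
#'   supplied.
#' @param fs Optional sampling rate (Hz) used to annotate dominant
#'   frequencies.
#' @export
iceemdan_decompose <- function(signal, cfg = iceemdan_config(), fs = NA_real_) {
  stopifnot(inherits(cfg, "iceemdan_config"))
  x <- as.numeric(signal)
  n <- length(x)
  sd_x <- stats::sd(x)
  if (sd_x == 0 || count_extrema(x) < 2) {
    return(imf_set(matrix(numeric(0), n, 0), x, fs = fs))
  }
  alpha <- cfg$noise_std_ratio * sd_x
  # decompose each white-noise realization once; reuse its modes at every stage
  noise_modes <- vector("list", cfg$ensemble_size)
  for (i in seq_len(cfg$ensemble_size)) {
    w <- with_seed(derive_seed(cfg$seed, paste0("iceemdan-noise-", i)),
                   stats::rnorm(n))
    noise_modes[[i]] <- emd(w, max_imfs = cfg$max_imfs,
                            sift_stop_sd = cfg$sift_stop_sd)$imfs
  }
  residuals <- list()
  r_prev <- x
  e_in <- sum(x^2)
  for (k in seq_len(cfg$max_imfs)) {
    if (count_extrema(r_prev) < 3) break
    acc <- numeric(n)
    for (i in seq_len(cfg$ensemble_size)) {
      ek <- if (ncol(noise_modes[[i]]) >= k) noise_modes[[i]][, k] else numeric(n)
      acc <- acc + local_mean(r_prev + alpha * ek, cfg$sift_stop_sd)
    }
    r_k <- acc / cfg$ensemble_size
    # a numerically empty mode means the residual is already the trend
    if (sum((r_prev - r_k)^2) < 1e-12 * e_in) break
    residuals[[k]] <- r_k
    r_prev <- r_k
  }
  if (!length(residuals)) return(imf_set(matrix(numeric(0), n, 0), x, fs = fs))
  rs <- do.call(cbind, residuals)
  prev <- cbind(x, rs[, -ncol(rs), drop = FALSE])
  imfs <- prev - rs                      # IIMF_k = r_{k-1} - r_k
  colnames(imfs) <- paste0("IMF", seq_len(ncol(imfs)))
  imf_set(imfs, rs[, ncol(rs)], fs = fs)
}
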