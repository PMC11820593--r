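#' Imaging configuration
#'
#' Parameters for encoding a 1-D segment as a stacked 3-channel image:
#' Gramian angular difference field (GADF), Markov transition field (MTF)
#' and recurrence plot (RP).
#'
#' @param image_size Output side length. Default 100.
#' @param mtf_bins Number of quantile bins (Markov states). Default 8.
#' @param rp_epsilon Recurrence threshold in signal units. Default 30
#'   (meaningful on ADC-scale amplitudes; the RP is computed on the raw,
#'   unnormalized segment).
#' @param rp_embedding_m Embedding dimension. Default 1 (no embedding).
#' @param rp_delay_tau Embedding delay. Default 1.
#' @param compression `"paa"` (piecewise aggregate approximation to
#'   `image_size` points before encoding, so matrices are natively
#'   `image_size` square) or `"resize"` (encode at full length, then
#'   bilinear-resize).
#' @return Object of class `imaging_config`.
#' @export
imaging_config <- function(image_size = 100L, mtf_bins = 8L, rp_epsilon = 30,
                           rp_embedding_m = 1L, rp_delay_tau = 1L,
                           compression = c("paa", "resize")) {
  compression <- match.arg(compression)
  if (image_size < 2L) stop("image_size must be >= 2")
  if (mtf_bins < 2L) stop("mtf_bins must be >= 2")
  if (rp_epsilon < 0) stop("rp_epsilon must be nonnegative")
  structure(list(image_size = as.integer(image_size),
                 mtf_bins = as.integer(mtf_bins), rp_epsilon = rp_epsilon,
                 rp_embedding_m = as.integer(rp_embedding_m),
                 rp_delay_tau = as.integer(rp_delay_tau),
                 compression = compression),
            class = "imaging_config")
}

#' Piecewise aggregate approximation
#'
#' Compresses a series to `m` values, each the mean of one equal-length
#' frame (1800 samples at `m = 100` gives 18-sample frames). When the
#' length is not divisible by `m`, the last frame is padded by repeating
#' the final sample.
#'
#' @param segment Numeric vector.
#' @param m Output length.
#' @return Numeric vector of length `m`.
#' @export
paa_compress <- function(segment, m = 100L) {
  x <- as.numeric(segment)
  n <- length(x)
  if (n < m) stop("segment shorter than the requested PAA length")
  frame <- ceiling(n / m)
  if (n %% m != 0) x <- c(x, rep(x[n], frame * m - n))   # pad-last-frame
  colMeans(matrix(x, nrow = length(x) / m, ncol = m))
}

# rescale to [-1, 1] (clamped for numerical safety)
rescale_unit <- function(x) {
  rng <- range(x)
  if (rng[1] == rng[2]) stop("constant series cannot be rescaled to [-1, 1]")
  pmin(1, pmax(-1, 2 * (x - rng[1]) / (rng[2] - rng[1]) - 1))
}

#' Gramian angular difference field
#'
#' Rescales the series to `[-1, 1]`, maps each value to a polar angle
#' `phi = arccos(x)`, and returns `G[i, j] = sin(phi_i - phi_j)`. The
#' diagonal is exactly zero and the matrix is antisymmetric.
#'
#' @param series Numeric vector with `max > min`.
#' @return Square matrix with entries in `[-1, 1]`.
#' @export
gadf <- function(series) {
  x <- rescale_unit(as.numeric(series))
  s <- sqrt(pmax(0, 1 - x^2))      # sin(arccos(x))
  G <- outer(s, x) - outer(x, s)   # sin(phi_i - phi_j)
  diag(G) <- 0
  G
}

#' Markov transition field
#'
#' Quantile-bins the series into `Q` states, fits a first-order Markov
#' chain to adjacent pairs (rows of the transition matrix `W` normalized to
#' 1), and returns `M[i, j] = W[state(i), state(j)]`. Duplicate quantile
#' breaks (few distinct values) merge the empty bins; a state with no
#' outgoing transition gets a uniform row.
#'
#' @param series Numeric vector, length >= 2.
#' @param Q Number of bins. Default 8.
#' @return List with `mtf` (the field) and `W` (the Q x Q row-stochastic
#'   transition matrix actually fitted).
#' @export
mtf <- function(series, Q = 8L) {
  x <- as.numeric(series)
  n <- length(x)
  if (n < 2) stop("series must have length >= 2")
  if (Q < 2) stop("Q must be >= 2")
  br <- unique(stats::quantile(x, probs = seq(0, 1, length.out = Q + 1),
                               names = FALSE, type = 7))
  if (length(br) < 3) {                    # essentially one distinct value
    state <- rep(1L, n)
    q <- 1L
  } else {
    state <- findInterval(x, br[-c(1, length(br))], left.open = FALSE) + 1L
    q <- length(br) - 1L
  }
  W <- matrix(0, q, q)
  for (t in seq_len(n - 1)) W[state[t], state[t + 1]] <- W[state[t], state[t + 1]] + 1
  rs <- rowSums(W)
  for (a in seq_len(q)) {
    W[a, ] <- if (rs[a] > 0) W[a, ] / rs[a] else rep(1 / q, q)
  }
  M <- matrix(W[cbind(rep(state, times = n), rep(state, each = n))], n, n)
  list(mtf = M, W = W)
}

#' Recurrence plot
#'
#' Delay-embeds the series (`m`, `tau`; default `m = 1` uses the raw
#' values) and marks pairs of points whose Euclidean distance is within
#' the threshold: `R[i, j] = 1` if `||x_i - x_j|| <= epsilon`. Symmetric
#' with unit diagonal. The series is used at its native amplitude, so the
#' default `epsilon = 30` refers to raw signal units.
#'
#' @param series Numeric vector.
#' @param epsilon Recurrence threshold. Default 30.
#' @param m Embedding dimension. Default 1.
#' @param tau Embedding delay. Default 1.
#' @param normalize If `TRUE`, rescale the series to `[-1, 1]` first.
#' @return Binary matrix of side `length(series) - (m - 1) * tau`.
#' @export
rp <- function(series, epsilon = 30, m = 1L, tau = 1L, normalize = FALSE) {
  x <- as.numeric(series)
  if (normalize) x <- rescale_unit(x)
  n_emb <- length(x) - (m - 1L) * tau
  if (n_emb < 2) stop("m and tau leave fewer than 2 embedded points")
  E <- vapply(seq_len(m), function(k) x[(seq_len(n_emb)) + (k - 1L) * tau],
              numeric(n_emb))
  if (is.vector(E)) E <- matrix(E, ncol = m)
  D2 <- as.matrix(stats::dist(E))^2
  R <- (D2 <= epsilon^2) * 1L
  diag(R) <- 1L
  dimnames(R) <- NULL
  R
}

# bilinear resize of a matrix to size out x out
bilinear_resize <- function(M, out) {
  n <- nrow(M); p <- ncol(M)
  if (n == out && p == out) return(M)
  ri <- seq(1, n, length.out = out)
  ci <- seq(1, p, length.out = out)
  r0 <- pmin(floor(ri), n - 1L); c0 <- pmin(floor(ci), p - 1L)
  fr <- ri - r0; fc <- ci - c0
  M00 <- M[r0, c0]; M10 <- M[r0 + 1, c0]
  M01 <- M[r0, c0 + 1]; M11 <- M[r0 + 1, c0 + 1]
  (1 - fr) %o% (1 - fc) * M00 + fr %o% (1 - fc) * M10 +
    (1 - fr) %o% fc * M01 + fr %o% fc * M11
}

#' Encode a segment as a GADF/MTF/RP image triplet
#'
#' Under `compression = "paa"` the segment is first compressed to
#' `image_size` points so the three encodings are natively square of the
#' right size; under `"resize"` the encodings are computed at full length
#' and bilinearly resized. The RP channel sees the raw amplitudes (so
#' `rp_epsilon` is in signal units); GADF and MTF internally normalize.
#'
#' @param segment Numeric vector (e.g. one 1800-sample slice).
#' @param cfg An [imaging_config()].
#' @return An `image_triplet`: list with `gadf`, `mtf`, `rp` matrices and
#'   `rgb` (8-bit integer array `image_size x image_size x 3`).
#' @export
encode_segment <- function(segment, cfg = imaging_config()) {
  stopifnot(inherits(cfg, "imaging_config"))
  sz <- cfg$image_size
  if (cfg$compression == "paa") {
    s <- paa_compress(segment, sz)
    g <- gadf(s)
    m_ <- mtf(s, cfg$mtf_bins)$mtf
    r <- rp(s, cfg$rp_epsilon, cfg$rp_embedding_m, cfg$rp_delay_tau)
    if (nrow(r) != sz) r <- bilinear_resize(r, sz)   # m > 1 shrinks the plot
  } else {
    g <- bilinear_resize(gadf(segment), sz)
    m_ <- bilinear_resize(mtf(segment, cfg$mtf_bins)$mtf, sz)
    r <- bilinear_resize(rp(segment, cfg$rp_epsilon, cfg$rp_embedding_m,
                            cfg$rp_delay_tau), sz)
  }
  structure(list(gadf = g, mtf = m_, rp = r, rgb = stack_rgb(g, m_, r)),
            class = "image_triplet")
}

#' Stack GADF/MTF/RP matrices into an 8-bit RGB image
#'
#' Channel maps (rounding half-up): GADF `[-1,1] -> [0,255]` into R, MTF
#' `[0,1] -> [0,255]` into G, RP `{0,1} -> {0,255}` into B.
#'
#' @param gadf,mtf,rp Square matrices of identical size.
#' @return Integer array `size x size x 3` with values in 0..255.
#' @export
stack_rgb <- function(gadf, mtf, rp) {
  if (!all(dim(gadf) == dim(mtf)) || !all(dim(gadf) == dim(rp)))
    stop("channel size mismatch")
  n <- nrow(gadf)
  out <- array(0L, c(n, n, 3))
  out[, , 1] <- as.integer(round_half_up((gadf + 1) / 2 * 255))
  out[, , 2] <- as.integer(round_half_up(pmin(1, pmax(0, mtf)) * 255))
  out[, , 3] <- as.integer(round_half_up(rp * 255))
  out
}

#' Write an image triplet to PNG for inspection
#'
#' @param triplet An `image_triplet` from [encode_segment()].
#' @param path Output PNG path.
#' @return Invisibly, `path`. Requires the `png` package.
#' @export
write_triplet_png <- function(triplet, path) {
  if (!requireNamespace("png", quietly = TRUE))
    stop("the png package is required for PNG export")
  png::writePNG(triplet$rgb / 255, path)
  invisible(path)
}

#' Encode every segment of a set
#'
#' @param segset A [segment_set()].
#' @param cfg An [imaging_config()].
#' @param scale Amplitude multiplier applied before encoding (use the ADC
#'   gain when segments are in physical units so `rp_epsilon = 30` keeps
#'   its raw-unit meaning). Default 1.
#' @return Numeric array `n x size x size x 3` of 8-bit values.
#' @export
encode_segments <- function(segset, cfg = imaging_config(), scale = 1) {
  stopifnot(inherits(segset, "segment_set"))
  n <- nrow(segset$segments)
  out <- array(0, c(n, cfg$image_size, cfg$image_size, 3))
  for (i in seq_len(n)) {
    out[i, , , ] <- encode_segment(segset$segments[i, ] * scale, cfg)$rgb
  }
  out
}
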