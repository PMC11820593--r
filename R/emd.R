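# Empirical mode decomposition: the sifting engine underlying ICEEMDAN.
#
# Envelope construction uses natural cubic splines through the local
# extrema with mirrored boundary extrema (two extrema reflected at each
# end) to suppress end swings; sifting stops when the normalized squared
# change (SD) drops below `sift_stop_sd` or after `max_sift` passes.

# indices of strict local maxima/minima (plateaus take their midpoint)
find_extrema <- function(x) {
  n <- length(x)
  if (n < 3) return(list(max = integer(), min = integer()))
  d <- diff(x)
  # collapse zero slopes so plateau edges count once
  nz <- which(d != 0)
  if (length(nz) < 2) return(list(max = integer(), min = integer()))
  s <- sign(d[nz])
  turn <- which(diff(s) != 0)
  idx <- nz[turn] + 1L
  is_max <- s[turn] > 0
  list(max = idx[is_max], min = idx[!is_max])
}

# upper/lower envelope mean via natural cubic splines with mirrored ends
envelope_mean <- function(x) {
  n <- length(x)
  ext <- find_extrema(x)
  if (length(ext$max) < 2 || length(ext$min) < 2) return(NULL)
  extend <- function(idx, val) {
    # mirror up to two extrema about each end point
    k <- min(2L, length(idx))
    left_i <- 2L - rev(idx[seq_len(k)])          # reflect about sample 1
    left_v <- rev(val[seq_len(k)])
    ri <- idx[(length(idx) - k + 1L):length(idx)]
    right_i <- 2L * n - rev(ri)                  # reflect about sample n
    right_v <- rev(val[(length(val) - k + 1L):length(val)])
    list(i = c(left_i, idx, right_i), v = c(left_v, val, right_v))
  }
  up <- extend(ext$max, x[ext$max])
  lo <- extend(ext$min, x[ext$min])
  upper <- stats::spline(up$i, up$v, xout = seq_len(n), method = "natural")$y
  lower <- stats::spline(lo$i, lo$v, xout = seq_len(n), method = "natural")$y
  (upper + lower) / 2
}

count_extrema <- function(x) {
  e <- find_extrema(x)
  length(e$max) + length(e$min)
}

count_zero_crossings <- function(x) {
  s <- sign(x)
  s <- s[s != 0]
  sum(diff(s) != 0)
}

# sift one IMF out of x; returns NULL when x has too few extrema.
# Stops when the envelope-mean change is small (SD criterion) AND the
# candidate satisfies the IMF count property (|#extrema - #zero
# crossings| <= 1), or after max_sift passes.
sift_imf <- function(x, sift_stop_sd = 0.2, max_sift = 30L) {
  h <- x
  for (it in seq_len(max_sift)) {
    m <- envelope_mean(h)
    if (is.null(m)) {
      if (it == 1L) return(NULL)
      break
    }
    h_new <- h - m
    sd_val <- sum((h - h_new)^2) / max(sum(h^2), .Machine$double.eps)
    h <- h_new
    if (sd_val < sift_stop_sd &&
        abs(count_extrema(h) - count_zero_crossings(h)) <= 1L) break
  }
  h
}

#' Empirical mode decomposition
#'
#' Decomposes a signal into intrinsic mode functions (IMFs) by iterative
#' sifting: each IMF is extracted by repeatedly subtracting the mean of the
#' cubic-spline envelopes through the local maxima and minima until the
#' envelope mean is negligible, then removed from the running residual.
#' The components are naturally ordered from high to low frequency and
#' satisfy the exact identity `rowSums(imfs) + residual == signal`.
#'
#' @param signal Numeric vector, length >= 8 with at least 2 extrema. A
#'   monotone (or constant) signal yields zero IMFs and `residual = signal`.
#' @param max_imfs Maximum number of IMFs to extract.
#' @param sift_stop_sd Sifting stop criterion: normalized squared change
#'   between consecutive sifts. Default 0.2 (classical).
#' @param max_sift Maximum sifting passes per IMF. Default 30.
#' @return An `imf_set`: list with `imfs` (matrix, one column per IMF,
#'   possibly 0 columns), `residual`, and `dominant_freq_hz` (filled by
#'   callers that know the sampling rate; `NA` here).
#' @export
emd <- function(signal, max_imfs = 12L, sift_stop_sd = 0.2, max_sift = 30L) {
  x <- as.numeric(signal)
  imfs <- list()
  resid <- x
  while (length(imfs) < max_imfs && count_extrema(resid) >= 3) {
    imf <- sift_imf(resid, sift_stop_sd, max_sift)
    if (is.null(imf)) break
    imfs[[length(imfs) + 1L]] <- imf
    resid <- resid - imf
  }
  imf_set(if (length(imfs)) do.call(cbind, imfs) else
            matrix(numeric(0), nrow = length(x), ncol = 0),
          resid)
}

#' IMF set container
#'
#' @param imfs Matrix with one column per intrinsic mode function.
#' @param residual Residual (trend) component.
#' @param fs Optional sampling rate; when given, per-component dominant
#'   frequencies are estimated by FFT peak.
#' @return Object of class `imf_set`.
#' @export
imf_set <- function(imfs, residual, fs = NA_real_) {
  stopifnot(is.matrix(imfs), nrow(imfs) == length(residual))
  df <- if (!is.na(fs) && ncol(imfs) > 0) {
    apply(imfs, 2, dominant_frequency, fs = fs)
  } else rep(NA_real_, ncol(imfs))
  structure(list(imfs = imfs, residual = as.numeric(residual),
                 dominant_freq_hz = df, fs = fs),
            class = "imf_set")
}

#' @export
print.imf_set <- function(x, ...) {
  cat(sprintf("<imf_set> %d IMF(s) + residual, n = %d\n",
              ncol(x$imfs), length(x$residual)))
  if (!all(is.na(x$dominant_freq_hz)))
    cat("  dominant freqs (Hz):",
        paste(signif(x$dominant_freq_hz, 3), collapse = " "), "\n")
  invisible(x)
}

#' Dominant frequency of a component by FFT peak
#'
#' @param x Numeric vector.
#' @param fs Sampling rate in Hz.
#' @return Frequency (Hz) of the largest non-DC spectral magnitude; 0 for a
#'   (numerically) constant component.
#' @export
dominant_frequency <- function(x, fs) {
  n <- length(x)
  if (n < 4 || stats::sd(x) < 1e-12 * (abs(mean(x)) + 1)) return(0)
  spec <- Mod(stats::fft(x - mean(x)))[2:(n %/% 2 + 1)]
  (which.max(spec)) * fs / n
}
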