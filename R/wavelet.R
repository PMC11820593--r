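# Discrete wavelet transform with sym8 (Symlet-8, 16-tap) filters and
# periodized boundary handling, which keeps the transform exactly
# orthogonal: n samples in, n coefficients out per level pair, perfect
# reconstruction to machine precision.

# Symlet-8 decomposition low-pass filter (standard Daubechies construction,
# least-asymmetric family, 8 vanishing moments).
.sym8_dec_lo <- c(
  -0.0033824159510061256, -0.0005421323317911481, 0.03169508781149298,
  0.007607487324917605, -0.1432942383508097, -0.061273359067658524,
  0.4813596512583722, 0.7771857517005235, 0.3644418948353314,
  -0.05194583810770904, -0.027219029917056003, 0.049137179673607506,
  0.003808752013890615, -0.01495225833704823, -0.0003029205147213668,
  0.0018899503327594609)

# quadrature mirror: g[k] = (-1)^k h[L-1-k]
.sym8_dec_hi <- rev(.sym8_dec_lo) * (-1)^(seq_along(.sym8_dec_lo) - 1)
.sym8_rec_lo <- rev(.sym8_dec_lo)
.sym8_rec_hi <- rev(.sym8_dec_hi)

# one periodized analysis step: x (even length) -> list(approx, detail),
# each length n/2. Convention matches the standard pyramid algorithm:
# a[k] = sum_m h[m] x[(2k + m - 1) mod n].
dwt_step <- function(x, lo = .sym8_dec_lo, hi = .sym8_dec_hi) {
  n <- length(x)
  stopifnot(n %% 2 == 0)
  L <- length(lo)
  half <- n / 2
  a <- numeric(half); d <- numeric(half)
  for (m in seq_len(L)) {
    idx <- ((2 * seq_len(half) - 2 + (m - 1)) %% n) + 1
    a <- a + lo[m] * x[idx]
    d <- d + hi[m] * x[idx]
  }
  list(approx = a, detail = d)
}

# inverse of dwt_step
idwt_step <- function(a, d, lo = .sym8_dec_lo, hi = .sym8_dec_hi) {
  half <- length(a)
  n <- 2 * half
  L <- length(lo)
  x <- numeric(n)
  for (m in seq_len(L)) {
    idx <- ((2 * seq_len(half) - 2 + (m - 1)) %% n) + 1
    x[idx] <- x[idx] + lo[m] * a + hi[m] * d
  }
  x
}

# multilevel analysis: returns list(approx, details = list(d1..dJ))
# where d1 is the finest scale. Length must be divisible by 2^levels.
wavelet_decompose <- function(x, levels = 5L) {
  n <- length(x)
  if (n %% 2^levels != 0)
    stop("signal length must be divisible by 2^levels for the periodized DWT")
  details <- vector("list", levels)
  a <- x
  for (j in seq_len(levels)) {
    s <- dwt_step(a)
    details[[j]] <- s$detail
    a <- s$approx
  }
  list(approx = a, details = details, levels = levels, n = n)
}

wavelet_reconstruct <- function(dec) {
  a <- dec$approx
  for (j in rev(seq_len(dec$levels))) {
    a <- idwt_step(a, dec$details[[j]])
  }
  a
}

#' Threshold parameters for wavelet denoising
#'
#' @param T Nonnegative threshold in coefficient units, or `NULL` to use
#'   the per-level universal threshold
#'   `sigma * sqrt(2 log n)`, `sigma = median(|detail|) / 0.6745`.
#' @param wavelet_name Wavelet family; only `"sym8"` is built in.
#' @param levels Decomposition depth. Default 5.
#' @return Object of class `threshold_params`.
#' @export
threshold_params <- function(T = NULL, wavelet_name = "sym8", levels = 5L) {
  if (!is.null(T) && T < 0) stop("threshold T must be nonnegative")
  if (wavelet_name != "sym8") stop("only the sym8 wavelet is provided")
  if (levels < 1) stop("levels must be >= 1")
  structure(list(T = T, wavelet_name = wavelet_name, levels = as.integer(levels)),
            class = "threshold_params")
}

#' Improved wavelet threshold function
#'
#' A continuous compromise between soft and hard thresholding:
#' \deqn{f(x) = \mathrm{sign}(x)\left(|x| - \frac{2T}{e^{(|x|-T)/T} + 1}\right)}
#' for \eqn{|x| \ge T} and 0 otherwise. At \eqn{|x| \to T^+} it behaves like
#' the soft threshold \eqn{\mathrm{sign}(x)(|x|-T)} (and is continuous,
#' \eqn{f(\pm T)=0}); as \eqn{|x| \to \infty} it approaches the identity
#' (hard threshold). The function is odd and shrinks: \eqn{|f(x)| \le |x|}.
#' `T = 0` degenerates to the identity (pass-through).
#'
#' @param x Numeric vector of wavelet coefficients.
#' @param T Nonnegative threshold.
#' @return Thresholded coefficients, same length as `x`.
#' @export
#' @examples
#' improved_threshold(c(-2, -0.5, 0, 0.5, 2), T = 1)
improved_threshold <- function(x, T) {
  stopifnot(T >= 0)
  if (T == 0) return(x)
  ax <- abs(x)
  out <- numeric(length(x))
  keep <- ax >= T
  out[keep] <- sign(x[keep]) * (ax[keep] - 2 * T / (exp((ax[keep] - T) / T) + 1))
  out
}

# universal threshold from the detail coefficients of one level
universal_threshold <- function(d, n) {
  sigma <- stats::median(abs(d)) / 0.6745
  sigma * sqrt(2 * log(n))
}

#' Wavelet-threshold one signal component
#'
#' 5-level (by default) sym8 decomposition; the improved threshold function
#' is applied to every detail level — with the per-level universal
#' threshold unless `params$T` fixes one globally — and the approximation
#' band is left untouched. Signals whose length is not divisible by
#' `2^levels` are zero-padded for the transform and trimmed after
#' reconstruction.
#'
#' @param component Numeric vector, length >= `2^levels`.
#' @param params A [threshold_params()].
#' @return Denoised component, same length as the input.
#' @export
wavelet_denoise_component <- function(component, params = threshold_params()) {
  stopifnot(inherits(params, "threshold_params"))
  x <- as.numeric(component)
  n <- length(x)
  block <- 2^params$levels
  if (n < block)
    stop("component shorter than 2^levels (= ", block, ") samples")
  pad <- (block - n %% block) %% block
  xp <- if (pad) c(x, numeric(pad)) else x
  dec <- wavelet_decompose(xp, params$levels)
  for (j in seq_len(params$levels)) {
    d <- dec$details[[j]]
    T_j <- if (is.null(params$T)) universal_threshold(d, length(xp)) else params$T
    dec$details[[j]] <- improved_threshold(d, T_j)
  }
  wavelet_reconstruct(dec)[seq_len(n)]
}
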