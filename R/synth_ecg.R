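#' Configuration for the synthetic ECG generator
#'
#' Defines the study conditions for generated records: sampling rate,
#' duration, the mix of AAMI beat classes, and heart rate. Beat classes are
#' drawn i.i.d. from `class_mix`; each beat is rendered as a sum of Gaussian
#' bumps (P/QRS/T-like) with class-specific width, amplitude and prematurity
#' so classes are morphologically distinct and the R-peak annotation index
#' is exact.
#'
#' @param sampling_rate_hz Sampling frequency in Hz. Default 360, matching
#'   the ambulatory recordings the pipeline targets.
#' @param duration_s Record duration in seconds; `sampling_rate_hz *
#'   duration_s` must be a whole number of samples.
#' @param class_mix Named numeric vector of class proportions over
#'   `c("N","S","V","F","Q")` (subsets allowed); nonnegative, summing to 1.
#' @param beat_rate_bpm Mean heart rate in beats per minute. Default 72.
#' @param seed Integer seed; generation is bit-reproducible given the seed.
#' @return An object of class `synth_config`.
#' @export
#' @examples
#' cfg <- synth_config(duration_s = 10, seed = 1)
#' rec <- generate_clean_record(cfg)
synth_config <- function(sampling_rate_hz = 360, duration_s = 30,
                         class_mix = c(N = 1), beat_rate_bpm = 72,
                         seed = 1L) {
  stopifnot(sampling_rate_hz > 0, duration_s > 0, beat_rate_bpm > 0)
  if (is.null(names(class_mix)) || !all(names(class_mix) %in% c("N", "S", "V", "F", "Q")))
    stop("class_mix must be named with AAMI labels N,S,V,F,Q")
  if (any(class_mix < 0) || abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix proportions must be nonnegative and sum to 1")
  n <- sampling_rate_hz * duration_s
  if (abs(n - round(n)) > 1e-9)
    stop("sampling_rate_hz * duration_s must be a whole number of samples")
  structure(list(sampling_rate_hz = sampling_rate_hz, duration_s = duration_s,
                 class_mix = class_mix, beat_rate_bpm = beat_rate_bpm,
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Noise model for synthetic ECG
#'
#' Additive noise with the three families that dominate ambulatory ECG:
#' sinusoidal baseline wander (kept strictly below 1.5 Hz so the
#' low-frequency cleaning rule of [denoise_record()] can remove it),
#' broadband Gaussian noise at a target SNR, and powerline interference.
#'
#' @param baseline_amp Baseline-wander amplitude (signal units). Default 0.
#' @param baseline_freq_hz Baseline-wander frequency, must lie in (0, 1.5).
#' @param gaussian_snr_db Target SNR of the Gaussian component in dB
#'   relative to the clean signal power; `Inf` disables it.
#' @param powerline_freq_hz Powerline frequency, 50 or 60 Hz.
#' @param powerline_amp Powerline amplitude (signal units). Default 0.
#' @param seed Integer seed.
#' @return An object of class `noise_spec`.
#' @export
noise_spec <- function(baseline_amp = 0, baseline_freq_hz = 0.5,
                       gaussian_snr_db = Inf, powerline_freq_hz = 50,
                       powerline_amp = 0, seed = 1L) {
  stopifnot(is.finite(baseline_amp), is.finite(powerline_amp))
  if (baseline_freq_hz <= 0 || baseline_freq_hz >= 1.5)
    stop("baseline_freq_hz must lie in (0, 1.5)")
  if (!powerline_freq_hz %in% c(50, 60))
    stop("powerline_freq_hz must be 50 or 60")
  structure(list(baseline_amp = baseline_amp, baseline_freq_hz = baseline_freq_hz,
                 gaussian_snr_db = gaussian_snr_db,
                 powerline_freq_hz = powerline_freq_hz,
                 powerline_amp = powerline_amp, seed = as.integer(seed)),
            class = "noise_spec")
}

# Class-specific beat morphology parameters, in seconds / millivolt-scale
# units. Widths are Gaussian sigmas. S beats are narrow and premature, V
# beats wide and large with inverted T and no P, F intermediate, Q
# low-amplitude and atypical.
.beat_morphology <- list(
  N = list(p = c(amp = 0.12, mu = -0.18, sd = 0.025),
           q = c(amp = -0.12, mu = -0.035, sd = 0.010),
           r = c(amp = 1.00, mu = 0.000, sd = 0.012),
           s = c(amp = -0.20, mu = 0.035, sd = 0.010),
           t = c(amp = 0.30, mu = 0.24, sd = 0.050), premature = 0),
  S = list(p = c(amp = 0.05, mu = -0.12, sd = 0.015),
           q = c(amp = -0.10, mu = -0.030, sd = 0.009),
           r = c(amp = 0.85, mu = 0.000, sd = 0.009),
           s = c(amp = -0.18, mu = 0.030, sd = 0.009),
           t = c(amp = 0.22, mu = 0.20, sd = 0.040), premature = 0.18),
  V = list(p = c(amp = 0.00, mu = -0.18, sd = 0.025),
           q = c(amp = -0.25, mu = -0.080, sd = 0.030),
           r = c(amp = 1.30, mu = 0.000, sd = 0.045),
           s = c(amp = -0.45, mu = 0.090, sd = 0.035),
           t = c(amp = -0.40, mu = 0.30, sd = 0.070), premature = 0.12),
  F = list(p = c(amp = 0.06, mu = -0.17, sd = 0.022),
           q = c(amp = -0.18, mu = -0.050, sd = 0.018),
           r = c(amp = 1.10, mu = 0.000, sd = 0.028),
           s = c(amp = -0.30, mu = 0.060, sd = 0.020),
           t = c(amp = 0.10, mu = 0.27, sd = 0.060), premature = 0.05),
  Q = list(p = c(amp = 0.03, mu = -0.15, sd = 0.030),
           q = c(amp = -0.05, mu = -0.060, sd = 0.025),
           r = c(amp = 0.45, mu = 0.000, sd = 0.060),
           s = c(amp = -0.08, mu = 0.070, sd = 0.030),
           t = c(amp = 0.08, mu = 0.26, sd = 0.080), premature = 0)
)

.render_beat <- function(t_rel, morph) {
  y <- numeric(length(t_rel))
  for (w in c("p", "q", "r", "s", "t")) {
    b <- morph[[w]]
    y <- y + b[["amp"]] * exp(-0.5 * ((t_rel - b[["mu"]]) / b[["sd"]])^2)
  }
  y
}

#' Generate a clean annotated synthetic ECG record
#'
#' Renders one quasi-periodic single-lead ECG at `cfg$sampling_rate_hz`.
#' Beats are placed at the nominal RR interval given by `beat_rate_bpm`
#' (class-dependent prematurity shifts ectopic beats earlier); each beat
#' contributes one annotation at its R-peak sample with its AAMI symbol.
#' The rendered record emulates the output of an AC-coupled,
#' baseline-corrected acquisition front end: its spectral content is
#' confined above 1.5 Hz, so the sub-1.5 Hz band is reserved for the
#' baseline-wander noise model ([noise_spec()]), mirroring the separation
#' that the low-frequency cleaning rule of [denoise_record()] assumes.
#'
#' @param cfg A [synth_config()].
#' @return An [ecg_record()] with one lead named `"synth"`.
#' @export
generate_clean_record <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  fs <- cfg$sampling_rate_hz
  n <- as.integer(round(fs * cfg$duration_s))
  rr <- 60 / cfg$beat_rate_bpm            # nominal RR interval, seconds
  if (cfg$duration_s < rr)
    stop("duration shorter than one beat interval")
  with_seed(cfg$seed, {
    # nominal R-peak times on a regular grid, first beat after a half RR
    base_times <- seq(rr * 0.5, cfg$duration_s - rr * 0.35, by = rr)
    labels <- sample(names(cfg$class_mix), length(base_times), replace = TRUE,
                     prob = cfg$class_mix)
    shift <- vapply(labels, function(l) .beat_morphology[[l]]$premature, 0)
    times <- base_times - shift * rr
    t_axis <- (seq_len(n) - 1) / fs
    sig <- numeric(n)
    for (i in seq_along(times)) {
      m <- .beat_morphology[[labels[i]]]
      lo <- max(1L, as.integer(floor((times[i] - 0.45) * fs)) + 1L)
      hi <- min(n, as.integer(ceiling((times[i] + 0.55) * fs)) + 1L)
      idx <- lo:hi
      sig[idx] <- sig[idx] + .render_beat(t_axis[idx] - times[i], m)
    }
    # emulate an AC-coupled, baseline-corrected front end: the clean
    # record's spectral content is confined above the baseline band, so
    # the sub-1.5 Hz band is reserved for the noise model
    sig <- highpass_fft(sig, fs, 1.5)
    ann_idx <- as.integer(round(times * fs))   # 0-based R-peak sample index
    keep <- ann_idx >= 0 & ann_idx < n
    ecg_record(signal = matrix(sig, ncol = 1,
                               dimnames = list(NULL, "synth")),
               fs = fs,
               annotations = data.frame(sample = ann_idx[keep],
                                        symbol = labels[keep],
                                        stringsAsFactors = FALSE))
  })
}

#' Add baseline wander, Gaussian noise and powerline interference
#'
#' The Gaussian component is rescaled so its realized power hits the target
#' SNR exactly (relative to the power of the input record's first lead);
#' baseline and powerline terms are deterministic sinusoids with a
#' seed-drawn phase. Annotations are unchanged.
#'
#' @param record An [ecg_record()].
#' @param spec A [noise_spec()].
#' @return The noisy record; attribute `"noise_components"` holds the three
#'   addends for oracle-style inspection.
#' @export
add_noise <- function(record, spec) {
  stopifnot(inherits(record, "ecg_record"), inherits(spec, "noise_spec"))
  n <- nrow(record$signal)
  if (n == 0L) stop("record is empty")
  t_axis <- (seq_len(n) - 1) / record$fs
  with_seed(spec$seed, {
    ph1 <- stats::runif(1, 0, 2 * pi)
    ph2 <- stats::runif(1, 0, 2 * pi)
    baseline <- spec$baseline_amp * sin(2 * pi * spec$baseline_freq_hz * t_axis + ph1)
    powerline <- spec$powerline_amp * sin(2 * pi * spec$powerline_freq_hz * t_axis + ph2)
    out <- record
    comps <- vector("list", ncol(record$signal))
    for (j in seq_len(ncol(record$signal))) {
      x <- record$signal[, j]
      if (is.finite(spec$gaussian_snr_db)) {
        p_sig <- mean(x^2)
        g <- stats::rnorm(n)
        target_p <- p_sig / 10^(spec$gaussian_snr_db / 10)
        g <- g * sqrt(target_p / mean(g^2))   # exact realized SNR
      } else g <- numeric(n)
      comps[[j]] <- list(baseline = baseline, gaussian = g, powerline = powerline)
      out$signal[, j] <- x + baseline + g + powerline
    }
    attr(out, "noise_components") <- comps
    out
  })
}
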