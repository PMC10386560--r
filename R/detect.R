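# Cardiac peak detection: SV principal signal (band-passed Hilbert envelope
# with adaptive thresholding in 5 s non-overlapping windows) and ECG R peaks
# (Engelse-Zeelenberg differentiator with the Lourenco-style adaptive
# threshold and refractory).

#' Detector configuration
#'
#' @param pre_band_hz band isolating the cardiac vibration content before the
#'   envelope (Hz, default `c(10, 40)`); respiratory sway dominates the raw
#'   displacement series, so this pre-filter is on by default.
#' @param pre_band_on logical switch for the pre-filter.
#' @param env_band_hz principal-signal band applied to the envelope (Hz,
#'   default `c(0.5, 3)`, i.e. 30-180 bpm).
#' @param window_s adaptive-threshold window length (s, default 5,
#'   non-overlapping).
#' @param thresh_frac acceptance threshold as a fraction of the running
#'   signal-peak level (default 0.25).
#' @param refractory_s minimum spacing between accepted peaks (s, default
#'   0.33, the period of the upper band edge).
#' @param filter_order Butterworth order, applied forward-backward
#'   (zero-phase), default 4.
#' @return a list of class `sv_detector_config`.
#' @export
detector_config <- function(pre_band_hz = c(10, 40), pre_band_on = TRUE,
                            env_band_hz = c(0.5, 3), window_s = 5,
                            thresh_frac = 0.25, refractory_s = 0.33,
                            filter_order = 4L) {
  if (window_s <= 0) stop("'window_s' must be positive")
  if (thresh_frac <= 0 || thresh_frac >= 1)
    stop("'thresh_frac' must be in (0, 1)")
  if (any(pre_band_hz <= 0) || diff(pre_band_hz) <= 0 ||
      any(env_band_hz <= 0) || diff(env_band_hz) <= 0)
    stop("filter bands must be increasing positive pairs")
  structure(list(pre_band_hz = pre_band_hz, pre_band_on = pre_band_on,
                 env_band_hz = env_band_hz, window_s = window_s,
                 thresh_frac = thresh_frac, refractory_s = refractory_s,
                 filter_order = as.integer(filter_order)),
            class = "sv_detector_config")
}

# zero-phase Butterworth band-pass
bandpass_zp <- function(x, band, rate, order) {
  nyq <- rate / 2
  if (band[2] >= nyq)
    stop(sprintf("band edge %.3g Hz at or above Nyquist (%.3g Hz)", band[2], nyq))
  bf <- signal::butter(order, band / nyq, type = "pass")
  signal::filtfilt(bf, x)
}

# Hilbert envelope: magnitude of the analytic signal via the FFT construction
hilbert_envelope <- function(x) {
  n <- length(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  Mod(fft(fft(x) * h, inverse = TRUE) / n)
}

#' Compute the SV principal signal
#'
#' The series on which cardiac peaks are detected: an optional zero-phase
#' band-pass to the cardiac vibration band, then the Hilbert envelope
#' (analytic-signal magnitude), then a zero-phase band-pass to the heart-rate
#' band (default 0.5-3 Hz). Both filter stages are zero-phase so peak timing
#' is preserved. Output length equals input length.
#'
#' @param dr displacement series (e.g. `trace$dr`).
#' @param rate_hz sampling rate.
#' @param cfg a [detector_config()].
#' @return numeric series, same length as `dr`.
#' @export
principal_signal <- function(dr, rate_hz, cfg = detector_config()) {
  stopifnot(inherits(cfg, "sv_detector_config"))
  if (length(dr) < 10 * rate_hz / cfg$env_band_hz[1])
    stop("record too short for the configured low band edge")
  x <- dr - mean(dr)
  if (cfg$pre_band_on && cfg$pre_band_hz[2] < rate_hz / 2)
    x <- bandpass_zp(x, cfg$pre_band_hz, rate_hz, cfg$filter_order)
  env <- hilbert_envelope(x)
  bandpass_zp(env, cfg$env_band_hz, rate_hz, cfg$filter_order)
}

# greedy refractory pass: among accepted peaks closer than refractory_s,
# keep the larger amplitude
enforce_refractory <- function(idx, amp, min_gap) {
  if (length(idx) < 2) return(idx)
  keep_i <- 1L
  out <- integer(0)
  for (i in 2:length(idx)) {
    if (idx[i] - idx[keep_i] < min_gap) {
      if (amp[i] > amp[keep_i]) keep_i <- i
    } else {
      out <- c(out, keep_i)
      keep_i <- i
    }
  }
  idx[sort(c(out, keep_i))]
}

#' Detect cardiac peaks in the SV principal signal
#'
#' Strict 3-point local maxima are accepted when they exceed the adaptive
#' threshold `thresh_frac x level`, where the running signal-peak `level` is
#' updated after each accepted peak as `0.125 * amplitude + 0.875 * level`
#' and the threshold is re-evaluated at the start of each non-overlapping
#' `window_s` window. Accepted peaks closer than `refractory_s` keep the
#' larger amplitude. All quantities are relative, so peak times are invariant
#' to a positive rescaling of the input.
#'
#' @param principal series from [principal_signal()].
#' @param rate_hz sampling rate.
#' @param cfg a [detector_config()].
#' @param t0 start timestamp carried onto the output (s).
#' @return a [beat_series()] (modality `"SV"`, 0-based sample indices).
#' @export
detect_sv_peaks <- function(principal, rate_hz, cfg = detector_config(),
                            t0 = 0) {
  stopifnot(inherits(cfg, "sv_detector_config"))
  n <- length(principal)
  empty <- beat_series(numeric(0), "SV", rate_hz, t0 = t0)
  if (n < 3 || max(principal) == min(principal)) return(empty)
  x <- principal
  cand <- which(x[2:(n - 1)] > x[1:(n - 2)] & x[2:(n - 1)] > x[3:n]) + 1L
  cand <- cand[x[cand] > 0]
  if (!length(cand)) return(empty)
  wlen <- round(cfg$window_s * rate_hz)
  first_w <- cand[cand <= wlen]
  level <- if (length(first_w)) max(x[first_w]) else max(x[cand])
  accepted <- integer(0)
  for (w0 in seq(1L, n, by = wlen)) {
    thr <- cfg$thresh_frac * level
    for (i in cand[cand >= w0 & cand < w0 + wlen]) {
      if (x[i] > thr) {
        accepted <- c(accepted, i)
        level <- 0.125 * x[i] + 0.875 * level
      }
    }
  }
  accepted <- enforce_refractory(accepted, x[accepted],
                                 cfg$refractory_s * rate_hz)
  beat_series(accepted - 1L, modality = "SV", rate_hz = rate_hz, t0 = t0)
}

#' Detect R peaks in a single-lead ECG
#'
#' Engelse-Zeelenberg scheme with Lourenco-style modifications: the signal is
#' differentiated (`y[n] = x[n] - x[n-4]`), smoothed with the 5-tap binomial
#' low-pass, and positive threshold crossings of the smoothed differentiator
#' open a 160 ms search window in which the R peak is taken as the signal
#' extremum. The crossing threshold is a fraction of a running peak level
#' (0.125/0.875 exponential update) and decays when no beat has been seen
#' for 1.5 s; accepted peaks are followed by a 200 ms refractory period.
#' Records whose rate differs from 300 Hz by more than 1% are resampled
#' internally to 300 Hz.
#'
#' @param ecg an [ecg_record()].
#' @return a [beat_series()] (modality `"ECG"`, 0-based sample indices at the
#'   working rate); empty with a warning for flat or peak-free input.
#' @export
detect_r_peaks <- function(ecg) {
  stopifnot(inherits(ecg, "ecg_record"))
  fs <- 300
  x <- ecg$samples
  if (abs(ecg$rate_hz - fs) / fs > 0.01) {
    n2 <- round(length(x) * fs / ecg$rate_hz)
    x <- stats::approx(seq_along(x), x, n = n2)$y
  }
  n <- length(x)
  if (n < fs || max(x) == min(x)) {
    warning("flat or too-short ECG: no R peaks detected")
    return(beat_series(numeric(0), "ECG", fs, t0 = ecg$t0))
  }
  x <- x - stats::median(x)
  # differentiator y1[n] = x[n] - x[n-4], then 5-tap binomial smoothing
  y1 <- c(numeric(4), x[5:n] - x[1:(n - 4)])
  y2 <- as.numeric(stats::filter(y1, c(1, 4, 6, 4, 1) / 16, sides = 1))
  y2[is.na(y2)] <- 0
  win <- round(0.16 * fs)
  refr <- round(0.20 * fs)
  decay_after <- round(1.5 * fs)
  level <- max(y2[1:min(n, 3 * fs)])
  if (level <= 0) {
    warning("no positive differentiator activity: no R peaks detected")
    return(beat_series(numeric(0), "ECG", fs, t0 = ecg$t0))
  }
  peaks <- integer(0)
  i <- 5L
  last_evt <- 0L
  while (i <= n - 1L) {
    thr <- 0.45 * level
    gap <- i - last_evt
    if (last_evt > 0L && gap > decay_after)
      thr <- thr * max(0.1, 1 - (gap - decay_after) / (2 * fs))
    if (y2[i] > thr) {
      j1 <- i; j2 <- min(n, i + win)
      p <- j1 - 1L + which.max(x[j1:j2])
      peaks <- c(peaks, p)
      level <- 0.125 * max(y2[j1:j2]) + 0.875 * level
      last_evt <- p
      i <- max(j2, p + refr) + 1L
    } else {
      i <- i + 1L
    }
  }
  if (!length(peaks)) {
    warning("no R peaks found above threshold")
    return(beat_series(numeric(0), "ECG", fs, t0 = ecg$t0))
  }
  peaks <- enforce_refractory(peaks, x[peaks], refr)
  beat_series(peaks - 1L, modality = "ECG", rate_hz = fs, t0 = ecg$t0)
}
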