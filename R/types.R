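#' Frame stack
#'
#' A time-ordered stack of equal-shape grayscale frames with a sampling rate,
#' the in-memory representation of a speckle video. Frames are stored as a
#' numeric 3-D array `rows x cols x n_frames`; integer camera data (8/16-bit)
#' is converted to floating intensity on construction.
#'
#' @param frames numeric 3-D array (`rows x cols x n`) or a list of equal-shape
#'   numeric matrices, all intensities non-negative.
#' @param rate_hz frame rate in frames per second (default 300).
#' @param t0 start timestamp in seconds (default 0).
#' @return an object of class `frame_stack` with elements `frames`, `rate_hz`,
#'   `t0`.
#' @examples
#' fs <- frame_stack(array(runif(16 * 16 * 3), c(16, 16, 3)))
#' n_frames(fs)
#' @export
frame_stack <- function(frames, rate_hz = 300, t0 = 0) {
  if (is.list(frames)) {
    shapes <- vapply(frames, function(f) paste(dim(as.matrix(f)), collapse = "x"), "")
    if (length(unique(shapes)) > 1L)
      stop("all frames must share one shape, got: ", paste(unique(shapes), collapse = ", "))
    frames <- array(unlist(frames, use.names = FALSE),
                    c(dim(as.matrix(frames[[1]])), length(frames)))
  }
  if (!is.array(frames) || length(dim(frames)) != 3L)
    stop("'frames' must be a 3-D array (rows x cols x frames) or a list of matrices")
  storage.mode(frames) <- "double"
  if (dim(frames)[3] < 2L)
    stop("a frame stack needs at least 2 frames (got ", dim(frames)[3], ")")
  if (!is.numeric(rate_hz) || length(rate_hz) != 1L || rate_hz <= 0)
    stop("'rate_hz' must be a single positive number")
  if (anyNA(frames) || any(frames < 0))
    stop("frame intensities must be finite and non-negative")
  structure(list(frames = frames, rate_hz = as.numeric(rate_hz), t0 = as.numeric(t0)),
            class = "frame_stack")
}

#' @rdname frame_stack
#' @param x a `frame_stack`.
#' @export
n_frames <- function(x) {
  stopifnot(inherits(x, "frame_stack"))
  dim(x$frames)[3]
}

#' @export
print.frame_stack <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<frame_stack> %d frames of %dx%d, %.6g frames/s, t0 = %.6g s (%.3g s)\n",
              d[3], d[1], d[2], x$rate_hz, x$t0, d[3] / x$rate_hz))
  invisible(x)
}

#' Imaging geometry of the near-focused speckle camera
#'
#' Holds the optical distances of the near-focused arrangement (camera focal
#' plane between the measured surface and the lens) that turn surface tilt
#' into speckle translation: a tilt `alpha` of the illuminated surface moves
#' the imaged speckle pattern by `K * tan(alpha)` metres on the sensor, i.e.
#' `K * tan(alpha) / pixel_pitch` pixels. By default `K = L1 * L2 / F`; pass
#' `K` directly to impose any other grouping of the three distances.
#'
#' @param L1 surface-to-focal-plane distance (m), default 0.8.
#' @param L2 focal-plane-to-lens distance (m), default 0.4.
#' @param F_len focal length of the imaging lens (m), default 0.05.
#' @param pixel_pitch sensor pixel size (m/pixel), default 5.86e-6.
#' @param K tilt-to-shift magnification (m of speckle shift per unit
#'   `tan(alpha)`); computed from `L1`, `L2`, `F_len` when `NULL`.
#' @return an object of class `sv_geometry`.
#' @examples
#' geometry()$K  # 0.8 * 0.4 / 0.05 = 6.4
#' @export
geometry <- function(L1 = 0.8, L2 = 0.4, F_len = 0.05, pixel_pitch = 5.86e-6,
                     K = NULL) {
  if (is.null(K)) K <- L1 * L2 / F_len
  vals <- c(L1 = L1, L2 = L2, F_len = F_len, pixel_pitch = pixel_pitch, K = K)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all geometry parameters must be positive and finite")
  structure(list(L1 = L1, L2 = L2, F_len = F_len,
                 pixel_pitch = pixel_pitch, K = K),
            class = "sv_geometry")
}

#' @export
print.sv_geometry <- function(x, ...) {
  cat(sprintf("<sv_geometry> L1 = %g m, L2 = %g m, F = %g m, pixel pitch = %g m, K = %g m\n",
              x$L1, x$L2, x$F_len, x$pixel_pitch, x$K))
  invisible(x)
}

#' Displacement trace
#'
#' Per-consecutive-frame-pair speckle shifts `(dx, dy)` in pixels (element k
#' is the shift from frame k to frame k+1, timestamped at frame k) and,
#' once [derive_dr()] has run, the orientation-independent series `dr`.
#'
#' @param dx,dy numeric vectors of per-pair shifts (pixels), equal length.
#' @param rate_hz sampling rate (the frame rate).
#' @param t0 start timestamp (s).
#' @param dr optional combined series, same length as `dx`.
#' @return an object of class `displacement_trace`.
#' @export
displacement_trace <- function(dx, dy, rate_hz, t0 = 0, dr = NULL) {
  if (length(dx) != length(dy))
    stop("'dx' and 'dy' must have equal length")
  if (!is.null(dr) && length(dr) != length(dx))
    stop("'dr' must have the same length as 'dx'")
  if (rate_hz <= 0) stop("'rate_hz' must be positive")
  structure(list(dx = as.numeric(dx), dy = as.numeric(dy),
                 dr = if (is.null(dr)) NULL else as.numeric(dr),
                 rate_hz = as.numeric(rate_hz), t0 = as.numeric(t0)),
            class = "displacement_trace")
}

#' @export
print.displacement_trace <- function(x, ...) {
  cat(sprintf("<displacement_trace> %d frame pairs at %.6g Hz, t0 = %.6g s, dr %s\n",
              length(x$dx), x$rate_hz, x$t0,
              if (is.null(x$dr)) "unset" else "set"))
  invisible(x)
}

#' Single-lead ECG record
#'
#' @param samples numeric amplitude series (arbitrary, mV-like units).
#' @param rate_hz sampling rate (Hz, default 300).
#' @param t0 start timestamp (s).
#' @return an object of class `ecg_record`.
#' @export
ecg_record <- function(samples, rate_hz = 300, t0 = 0) {
  if (!is.numeric(samples) || anyNA(samples) || any(!is.finite(samples)))
    stop("'samples' must be finite numeric values")
  if (rate_hz <= 0) stop("'rate_hz' must be positive")
  structure(list(samples = as.numeric(samples), rate_hz = as.numeric(rate_hz),
                 t0 = as.numeric(t0)),
            class = "ecg_record")
}

#' @export
print.ecg_record <- function(x, ...) {
  cat(sprintf("<ecg_record> %d samples at %.6g Hz, t0 = %.6g s (%.3g s)\n",
              length(x$samples), x$rate_hz, x$t0, length(x$samples) / x$rate_hz))
  invisible(x)
}

#' Beat series
#'
#' Strictly increasing cardiac peak times for one modality. Peaks are stored
#' as 0-based sample indices relative to the record start (exact integer
#' arithmetic for the matching algorithm); [peak_times()] converts to seconds.
#'
#' @param peaks strictly increasing numeric vector of peak positions
#'   (0-based samples relative to the record start).
#' @param modality `"SV"` or `"ECG"`.
#' @param rate_hz sampling rate of the underlying record.
#' @param t0 start timestamp of the underlying record (s).
#' @return an object of class `beat_series`.
#' @export
beat_series <- function(peaks, modality = c("SV", "ECG"), rate_hz, t0 = 0) {
  modality <- match.arg(modality)
  peaks <- as.numeric(peaks)
  if (length(peaks) && (anyNA(peaks) || is.unsorted(peaks, strictly = TRUE)))
    stop("'peaks' must be strictly increasing and finite")
  if (rate_hz <= 0) stop("'rate_hz' must be positive")
  structure(list(peaks = peaks, modality = modality,
                 rate_hz = as.numeric(rate_hz), t0 = as.numeric(t0)),
            class = "beat_series")
}

#' @rdname beat_series
#' @param x a `beat_series`.
#' @return for `peak_times()`, peak times in seconds (`t0 + peaks / rate_hz`).
#' @export
peak_times <- function(x) {
  stopifnot(inherits(x, "beat_series"))
  x$t0 + x$peaks / x$rate_hz
}

#' @export
print.beat_series <- function(x, ...) {
  cat(sprintf("<beat_series> %s: %d peaks at %.6g Hz", x$modality,
              length(x$peaks), x$rate_hz))
  if (length(x$peaks) > 1)
    cat(sprintf(", median interval %.3f s",
                stats::median(diff(x$peaks)) / x$rate_hz))
  cat("\n")
  invisible(x)
}

#' Matched ECG/SV beat pairs
#'
#' Output container of the one-to-one beat matcher: equal-length lists of
#' matched ECG peak positions (`m_valid`) and SV peak positions (`n_valid`),
#' plus the original detected counts used by recall/precision.
#'
#' @param m_valid,n_valid equal-length strictly increasing numeric vectors of
#'   matched peak positions (same unit as the inputs of [match_beats()]).
#' @param n_ecg_total,n_sv_total original detected peak counts.
#' @param rate_hz sampling rate (for unit conversion downstream).
#' @return an object of class `matched_beats`.
#' @export
matched_beats <- function(m_valid, n_valid, n_ecg_total, n_sv_total,
                          rate_hz = NA_real_) {
  if (length(m_valid) != length(n_valid))
    stop("'m_valid' and 'n_valid' must have equal length")
  if (length(m_valid) > 1 && (is.unsorted(m_valid, strictly = TRUE) ||
                              is.unsorted(n_valid, strictly = TRUE)))
    stop("matched peak lists must be strictly increasing")
  if (anyDuplicated(n_valid)) stop("an SV peak may be matched at most once")
  if (length(m_valid) > n_ecg_total || length(n_valid) > n_sv_total)
    stop("matched counts cannot exceed detected counts")
  structure(list(m_valid = as.numeric(m_valid), n_valid = as.numeric(n_valid),
                 n_ecg_total = as.integer(n_ecg_total),
                 n_sv_total = as.integer(n_sv_total),
                 rate_hz = as.numeric(rate_hz)),
            class = "matched_beats")
}

#' @export
print.matched_beats <- function(x, ...) {
  cat(sprintf("<matched_beats> %d pairs (of %d ECG / %d SV detected peaks)\n",
              length(x$m_valid), x$n_ecg_total, x$n_sv_total))
  invisible(x)
}

#' Paired inter-beat intervals
#'
#' Equal-length one-to-one mapped inter-beat intervals from the matched ECG
#' and SV peak lists, after exclusion of false intervals (intervals spanning
#' a discarded original R peak).
#'
#' @param ibi_ecg,ibi_sv equal-length positive interval lists (seconds).
#' @param kept_index integer positions (within the consecutive pairs of
#'   `m_valid`) that survived exclusion.
#' @return an object of class `ibi_pair`.
#' @export
ibi_pair <- function(ibi_ecg, ibi_sv, kept_index = seq_along(ibi_ecg)) {
  if (length(ibi_ecg) != length(ibi_sv))
    stop("'ibi_ecg' and 'ibi_sv' must have equal length")
  if (any(ibi_ecg <= 0) || any(ibi_sv <= 0))
    stop("all inter-beat intervals must be positive")
  structure(list(ibi_ecg = as.numeric(ibi_ecg), ibi_sv = as.numeric(ibi_sv),
                 kept_index = as.integer(kept_index)),
            class = "ibi_pair")
}

#' @export
print.ibi_pair <- function(x, ...) {
  cat(sprintf("<ibi_pair> %d paired intervals", length(x$ibi_ecg)))
  if (length(x$ibi_ecg))
    cat(sprintf(", mean IBI %.3f s (ECG) / %.3f s (SV)",
                mean(x$ibi_ecg), mean(x$ibi_sv)))
  cat("\n")
  invisible(x)
}
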