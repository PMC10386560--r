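#' Read a speckle video frame stack
#'
#' Reads a multi-page grayscale TIFF (`.tif`/`.tiff`) or a 3-D NPY array
#' (`.npy`, `frames x rows x cols`, C order as written by numpy) into a
#' [frame_stack()]. Integer pixel types are converted to floating intensity.
#'
#' @param path file path.
#' @param rate_hz frame rate to record on the stack (frames/s, default 300).
#' @param t0 start timestamp (s).
#' @return a [frame_stack()].
#' @seealso [write_frame_stack()]
#' @export
read_frame_stack <- function(path, rate_hz = 300, t0 = 0) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
    if (!is.list(pages)) pages <- list(pages)
    pages <- lapply(pages, function(p) {
      if (length(dim(p)) == 3L) p <- p[, , 1]  # collapse replicated gray channels
      p
    })
    return(frame_stack(pages, rate_hz = rate_hz, t0 = t0))
  }
  if (ext == "npy") {
    a <- read_npy(path)
    if (length(dim(a)) != 3L)
      stop("NPY stack must be 3-D (frames x rows x cols), got ",
           length(dim(a)), "-D")
    # stored frames-first; frame_stack wants rows x cols x frames
    return(frame_stack(aperm(a, c(2, 3, 1)), rate_hz = rate_hz, t0 = t0))
  }
  stop("unsupported frame-stack format: .", ext, " (use .tif/.tiff or .npy)")
}

#' Write a speckle video frame stack
#'
#' `.npy` stores float64 (lossless, bit-exact round-trip). `.tif`/`.tiff`
#' stores 16-bit grayscale after scaling intensities to `[0, 1]` by the stack
#' maximum; the scale factor is not kept, so the TIFF path preserves shape and
#' relative intensity only (sufficient for registration, which is invariant
#' to a global intensity scale).
#'
#' @param stack a [frame_stack()].
#' @param path output path, extension selects the format.
#' @return `path`, invisibly.
#' @export
write_frame_stack <- function(stack, path) {
  stopifnot(inherits(stack, "frame_stack"))
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tif", "tiff")) {
    mx <- max(stack$frames)
    scale <- if (mx > 0) mx else 1
    pages <- lapply(seq_len(n_frames(stack)),
                    function(k) stack$frames[, , k] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 16)
  } else if (ext == "npy") {
    write_npy(aperm(stack$frames, c(3, 1, 2)), path)
  } else {
    stop("unsupported frame-stack format: .", ext)
  }
  invisible(path)
}

#' Read a uniformly sampled signal from CSV
#'
#' Expects a header with columns `time_s` and `value`. The sampling rate is
#' inferred from the median time step; timestamps deviating from uniformity
#' by more than 1% of that step are rejected.
#'
#' @param path CSV file path.
#' @return an [ecg_record()] with `t0` taken from the first timestamp.
#' @export
read_signal_csv <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  d <- utils::read.csv(path)
  if (!all(c("time_s", "value") %in% names(d)))
    stop("signal CSV needs columns 'time_s' and 'value'")
  tt <- d$time_s
  if (length(tt) < 2L) stop("signal CSV needs at least 2 rows")
  dt <- diff(tt)
  if (any(dt <= 0)) stop("non-monotonic time column")
  step <- stats::median(dt)
  if (any(abs(dt - step) > 0.01 * step))
    stop("non-uniform sampling beyond 1% tolerance")
  ecg_record(d$value, rate_hz = 1 / step, t0 = tt[1])
}

#' @rdname read_signal_csv
#' @param rec an [ecg_record()] (or any list with `samples`, `rate_hz`, `t0`).
#' @param path output CSV path.
#' @export
write_signal_csv <- function(rec, path) {
  tt <- rec$t0 + (seq_along(rec$samples) - 1) / rec$rate_hz
  utils::write.csv(data.frame(time_s = tt, value = rec$samples),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read/write beat times as CSV (column `peak_time_s`)
#'
#' @param path CSV file path.
#' @param modality,rate_hz passed to [beat_series()] when reading.
#' @return for `read_beats_csv`, a [beat_series()] (peaks converted to
#'   samples at `rate_hz`).
#' @export
read_beats_csv <- function(path, modality = "SV", rate_hz = 300) {
  d <- utils::read.csv(path)
  if (!"peak_time_s" %in% names(d))
    stop("beats CSV needs column 'peak_time_s'")
  beat_series(d$peak_time_s * rate_hz, modality = modality, rate_hz = rate_hz)
}

#' @rdname read_beats_csv
#' @param beats a [beat_series()].
#' @export
write_beats_csv <- function(beats, path) {
  utils::write.csv(data.frame(peak_time_s = peak_times(beats)),
                   path, row.names = FALSE)
  invisible(path)
}

#' Read/write paired inter-beat intervals as CSV
#'
#' Columns `ibi_ecg_s`, `ibi_sv_s`.
#' @param path CSV file path.
#' @return for `read_ibi_csv`, an [ibi_pair()].
#' @export
read_ibi_csv <- function(path) {
  d <- utils::read.csv(path)
  if (!all(c("ibi_ecg_s", "ibi_sv_s") %in% names(d)))
    stop("IBI CSV needs columns 'ibi_ecg_s' and 'ibi_sv_s'")
  ibi_pair(d$ibi_ecg_s, d$ibi_sv_s)
}

#' @rdname read_ibi_csv
#' @param ibis an [ibi_pair()].
#' @export
write_ibi_csv <- function(ibis, path) {
  utils::write.csv(data.frame(ibi_ecg_s = ibis$ibi_ecg, ibi_sv_s = ibis$ibi_sv),
                   path, row.names = FALSE)
  invisible(path)
}

#' Crop an SV displacement trace and an ECG record to their common window
#'
#' Both inputs carry a start timestamp `t0` and a sampling rate; each is
#' cropped to the overlapping time window, with offsets resolved to the
#' nearest sample. Idempotent: aligning already-aligned inputs is a no-op.
#'
#' @param sv a [displacement_trace()].
#' @param ecg an [ecg_record()].
#' @return `list(sv = , ecg = )` with both cropped.
#' @export
align_by_timestamps <- function(sv, ecg) {
  stopifnot(inherits(sv, "displacement_trace"), inherits(ecg, "ecg_record"))
  sv_end <- sv$t0 + length(sv$dx) / sv$rate_hz
  ecg_end <- ecg$t0 + length(ecg$samples) / ecg$rate_hz
  start <- max(sv$t0, ecg$t0)
  end <- min(sv_end, ecg_end)
  if (start >= end) stop("no overlap between SV and ECG time windows")
  crop <- function(t0, rate, n) {
    i0 <- round((start - t0) * rate)
    i1 <- round((end - t0) * rate)
    c(max(0L, i0), min(n, i1))
  }
  s <- crop(sv$t0, sv$rate_hz, length(sv$dx))
  e <- crop(ecg$t0, ecg$rate_hz, length(ecg$samples))
  sv_idx <- (s[1] + 1L):s[2]
  sv2 <- displacement_trace(sv$dx[sv_idx], sv$dy[sv_idx], sv$rate_hz,
                            t0 = sv$t0 + s[1] / sv$rate_hz,
                            dr = if (is.null(sv$dr)) NULL else sv$dr[sv_idx])
  ecg2 <- ecg_record(ecg$samples[(e[1] + 1L):e[2]], ecg$rate_hz,
                     t0 = ecg$t0 + e[1] / ecg$rate_hz)
  list(sv = sv2, ecg = ecg2)
}

#' Pipeline configuration
#'
#' Returns the full default configuration as a nested list with sections
#' `geometry`, `filters`, `detector` and `simulation`; `read_sv_config()`
#' merges a YAML file (same section structure, any subset of keys) over these
#' defaults.
#'
#' @return nested configuration list of class `sv_config`.
#' @export
sv_config <- function() {
  structure(list(
    geometry = list(L1 = 0.8, L2 = 0.4, F_len = 0.05,
                    pixel_pitch = 5.86e-6, K = NULL),
    filters = list(upsampling = 100L, hann_window = FALSE),
    detector = list(pre_band_hz = c(10, 40), pre_band_on = TRUE,
                    env_band_hz = c(0.5, 3), window_s = 5,
                    thresh_frac = 0.25, refractory_s = 0.33,
                    filter_order = 4L),
    simulation = list(duration_s = 60, frame_rate_hz = 300, ecg_rate_hz = 300,
                      frame_shape = c(64L, 64L), grain_px = 4,
                      mean_hr_bpm = 60, sdnn_s = 0.03, rsa_depth = 0.05,
                      resp_rate_hz = 0.25, cardiac_tilt_amp_rad = 1e-6,
                      resp_tilt_amp_rad = 5e-6, noise_sd = 0.02,
                      damping = 1, shift_axis_deg = 30,
                      ecg_noise_sd = 0.01, seed = 1L)
  ), class = "sv_config")
}

#' @rdname sv_config
#' @param path YAML configuration file.
#' @export
read_sv_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  user <- yaml::read_yaml(path)
  cfg <- unclass(sv_config())
  for (sec in intersect(names(user), names(cfg))) {
    for (key in names(user[[sec]])) cfg[[sec]][[key]] <- user[[sec]][[key]]
  }
  structure(cfg, class = "sv_config")
}

#' Write pipeline results as JSON
#'
#' @param results named list (e.g. bias, sd, loa_low, loa_high, n, recall,
#'   precision).
#' @param path output path.
#' @export
write_results_json <- function(results, path) {
  jsonlite::write_json(results, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

sv_log <- function(fmt, ...) {
  message(sprintf(paste0("[svihr] ", fmt), ...))
}
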