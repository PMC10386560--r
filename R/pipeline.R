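#' Run the full speckle-vibrometry IHR pipeline
#'
#' Chains every stage from video to agreement: sub-pixel registration of
#' consecutive frames, reduction to the orientation-independent series Dr,
#' timestamp alignment with the ECG, the principal signal (band-passed
#' Hilbert envelope) and its adaptive-threshold cardiac peaks, ECG R peaks,
#' one-to-one beat matching, false-interval exclusion, and Bland-Altman
#' agreement between the two instantaneous heart rate series.
#'
#' @param frames a [frame_stack()] (speckle video).
#' @param ecg an [ecg_record()].
#' @param config a configuration from [sv_config()] or [read_sv_config()];
#'   the `filters` and `detector` sections are used.
#' @param verbose emit stage-level progress to standard error.
#' @return an object of class `sv_ihr` with components `trace` (with `dr`),
#'   `principal`, `sv_beats`, `r_beats`, `matched`, `recall`, `precision`,
#'   `ibis`, `agreement` (a [bland_altman()]), and `config`. Methods:
#'   `print`, `summary`, `coef` (bias, sd, LOA, recall, precision, n),
#'   `residuals` (paired IHR differences, ECG - SV), `plot` (Bland-Altman).
#' @export
sv_ihr <- function(frames, ecg, config = sv_config(), verbose = TRUE) {
  stopifnot(inherits(frames, "frame_stack"), inherits(ecg, "ecg_record"))
  say <- if (verbose) sv_log else function(...) invisible(NULL)
  det <- do.call(detector_config, config$detector[
    intersect(names(config$detector), names(formals(detector_config)))])
  ups <- config$filters$upsampling
  say("registering %d frame pairs (upsampling %d)", n_frames(frames) - 1, ups)
  trace <- extract_displacement_trace(frames, upsampling = ups,
                                      hann = isTRUE(config$filters$hann_window))
  trace <- derive_dr(trace)
  aligned <- align_by_timestamps(trace, ecg)
  say("aligned window: %.2f s of SV, %.2f s of ECG",
      length(aligned$sv$dr) / aligned$sv$rate_hz,
      length(aligned$ecg$samples) / aligned$ecg$rate_hz)
  principal <- principal_signal(aligned$sv$dr, aligned$sv$rate_hz, det)
  sv_beats <- detect_sv_peaks(principal, aligned$sv$rate_hz, det,
                              t0 = aligned$sv$t0)
  r_beats <- detect_r_peaks(aligned$ecg)
  say("detected %d SV peaks, %d R peaks",
      length(sv_beats$peaks), length(r_beats$peaks))
  matched <- match_beats(r_beats, sv_beats)
  rp <- compute_recall_precision(matched)
  ibis <- select_ibis(r_beats, matched)
  agreement <- bland_altman(ibi_to_ihr(ibis$ibi_ecg), ibi_to_ihr(ibis$ibi_sv))
  say("matched %d pairs (recall %.3f, precision %.3f), %d IBIs kept",
      length(matched$m_valid), rp["recall"], rp["precision"],
      length(ibis$ibi_ecg))
  structure(list(trace = aligned$sv, principal = principal,
                 sv_beats = sv_beats, r_beats = r_beats, matched = matched,
                 recall = unname(rp["recall"]),
                 precision = unname(rp["precision"]),
                 ibis = ibis, agreement = agreement, config = config,
                 call = match.call()),
            class = "sv_ihr")
}

#' @export
print.sv_ihr <- function(x, ...) {
  cat("Speckle-vibrometry IHR pipeline result\n")
  cat(sprintf("  %d SV peaks, %d R peaks, %d matched pairs, %d paired IBIs\n",
              length(x$sv_beats$peaks), length(x$r_beats$peaks),
              length(x$matched$m_valid), length(x$ibis$ibi_ecg)))
  cat(sprintf("  recall %.3f, precision %.3f\n", x$recall, x$precision))
  cat(sprintf("  IHR agreement: bias %.3f bpm, SD %.3f bpm, LOA [%.2f, %.2f] bpm\n",
              x$agreement$bias, x$agreement$sd,
              x$agreement$loa_low, x$agreement$loa_high))
  invisible(x)
}

#' @export
summary.sv_ihr <- function(object, ...) {
  print(object)
  ihr <- ibi_to_ihr(object$ibis$ibi_ecg)
  if (length(ihr)) {
    cat(sprintf("  ECG IHR: mean %.1f bpm, range [%.1f, %.1f] bpm\n",
                mean(ihr), min(ihr), max(ihr)))
    cat(sprintf("  mean |IHR difference|: %.3f bpm\n",
                mean(abs(object$agreement$diffs))))
  }
  invisible(object)
}

#' @export
coef.sv_ihr <- function(object, ...) {
  c(bias = object$agreement$bias, sd = object$agreement$sd,
    loa_low = object$agreement$loa_low, loa_high = object$agreement$loa_high,
    recall = object$recall, precision = object$precision,
    n = object$agreement$n)
}

#' @export
residuals.sv_ihr <- function(object, ...) object$agreement$diffs

#' @export
plot.sv_ihr <- function(x, ...) plot(x$agreement, ...)

#' Results of an `sv_ihr` run as a flat named list (for JSON export)
#'
#' @param fit an `sv_ihr` object.
#' @return named list: `bias`, `sd`, `loa_low`, `loa_high`, `n`, `recall`,
#'   `precision`.
#' @export
sv_ihr_results <- function(fit) {
  stopifnot(inherits(fit, "sv_ihr"))
  list(bias = fit$agreement$bias, sd = fit$agreement$sd,
       loa_low = fit$agreement$loa_low, loa_high = fit$agreement$loa_high,
       n = fit$agreement$n, recall = fit$recall, precision = fit$precision)
}
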