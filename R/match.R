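# One-to-one ECG/SV beat pairing and false-interval exclusion.

as_peak_values <- function(x, what) {
  if (inherits(x, "beat_series")) peak_times(x)
  else if (is.numeric(x)) as.numeric(x)
  else stop("'", what, "' must be a beat_series or a numeric vector")
}

#' Match ECG R peaks to SV cardiac peaks one-to-one
#'
#' For each R peak `m_j` a search interval is built from its neighbours:
#' `[0, m_1 + 0.4 (m_2 - m_1)]` for the first peak,
#' `[m_j - 0.4 (m_j - m_{j-1}), m_j + 0.4 (m_{j+1} - m_j)]` for interior
#' peaks, and `[m_j - 0.4 (m_j - m_{j-1}), m_j]` for the last. The factor 0.4
#' (rather than 0.5, the half distance to each neighbour) makes the interval
#' deliberately narrower than the gap between beats. Among the SV peaks
#' inside the interval (bounds inclusive) the one nearest to `m_j` is
#' selected, with an equidistant tie going to the earlier SV peak; if no SV
#' peak lies inside, or the nearest one was already selected for an earlier R
#' peak, the R peak is discarded with no fallback.
#'
#' @param m_ecg ECG R peaks: a [beat_series()] (used in seconds via
#'   [peak_times()]) or a strictly increasing numeric vector; at least 2
#'   peaks.
#' @param n_sv SV cardiac peaks, same convention and same unit as `m_ecg`.
#' @param rate_hz sampling rate recorded on the result for later unit
#'   conversion; defaults to 1 (values in seconds) when beat series are
#'   given, `NA` otherwise.
#' @return a [matched_beats()] with the paired lists and the original
#'   detected counts.
#' @export
match_beats <- function(m_ecg, n_sv, rate_hz = NULL) {
  if (is.null(rate_hz))
    rate_hz <- if (inherits(m_ecg, "beat_series")) 1 else NA_real_
  m <- as_peak_values(m_ecg, "m_ecg")
  n <- as_peak_values(n_sv, "n_sv")
  if (is.unsorted(m, strictly = TRUE) ||
      (length(n) > 1 && is.unsorted(n, strictly = TRUE)))
    stop("peak lists must be strictly increasing")
  J <- length(m)
  if (J < 2) stop("need at least 2 ECG peaks to define matching intervals")
  m_valid <- numeric(0)
  n_valid <- numeric(0)
  sel <- integer(0)
  for (j in seq_len(J)) {
    if (j == 1) {
      lo <- 0; hi <- m[1] + 0.4 * (m[2] - m[1])
    } else if (j < J) {
      lo <- m[j] - 0.4 * (m[j] - m[j - 1]); hi <- m[j] + 0.4 * (m[j + 1] - m[j])
    } else {
      lo <- m[j] - 0.4 * (m[j] - m[j - 1]); hi <- m[j]
    }
    cand <- which(n >= lo & n <= hi)
    if (!length(cand)) next
    pick <- cand[order(abs(n[cand] - m[j]), n[cand])][1]
    if (pick %in% sel) next
    sel <- c(sel, pick)
    m_valid <- c(m_valid, m[j])
    n_valid <- c(n_valid, n[pick])
  }
  matched_beats(m_valid, n_valid, n_ecg_total = J, n_sv_total = length(n),
                rate_hz = rate_hz)
}

#' Recall and precision of SV beat detection against ECG
#'
#' `recall = |Mvalid| / N_ECG` (fraction of detected R peaks that found an SV
#' partner) and `precision = |Nvalid| / N_SV` (fraction of detected SV peaks
#' that were matched).
#'
#' @param matched a [matched_beats()].
#' @return named numeric vector `c(recall = , precision = )`, both in
#'   `[0, 1]`.
#' @export
compute_recall_precision <- function(matched) {
  stopifnot(inherits(matched, "matched_beats"))
  if (matched$n_ecg_total == 0 || matched$n_sv_total == 0)
    stop("recall/precision undefined for zero detected peaks")
  c(recall = length(matched$m_valid) / matched$n_ecg_total,
    precision = length(matched$n_valid) / matched$n_sv_total)
}

#' Select paired inter-beat intervals, excluding false intervals
#'
#' Consecutive differences of the matched lists form candidate interval
#' pairs. An ECG interval that spans at least one original R peak discarded
#' during matching would merge two true beats into one artificially long
#' interval ("false interval"); such pairs are removed from both modalities
#' so that SV performance is not judged on intervals broken by its own
#' missed beats.
#'
#' @param n_ecg_all all originally detected R peaks (a [beat_series()] or
#'   numeric vector, same unit as the matcher output); every `m_valid` entry
#'   must be present in it.
#' @param matched a [matched_beats()] from [match_beats()].
#' @param rate_hz samples-per-second conversion for the stored peak values;
#'   defaults to the rate recorded on `matched` (1 when the matcher worked in
#'   seconds).
#' @return an [ibi_pair()] with intervals in seconds and the surviving
#'   consecutive-pair positions in `kept_index`.
#' @export
select_ibis <- function(n_ecg_all, matched, rate_hz = NULL) {
  stopifnot(inherits(matched, "matched_beats"))
  all_m <- as_peak_values(n_ecg_all, "n_ecg_all")
  if (is.null(rate_hz)) rate_hz <- matched$rate_hz
  if (is.na(rate_hz))
    stop("'rate_hz' needed to convert peak units to seconds")
  mv <- matched$m_valid
  nv <- matched$n_valid
  if (!all(mv %in% all_m))
    stop("'m_valid' must be a subset of the original R peaks")
  if (length(mv) < 2)
    return(ibi_pair(numeric(0), numeric(0), integer(0)))
  discarded <- setdiff(all_m, mv)
  keep <- vapply(seq_len(length(mv) - 1), function(k) {
    !any(discarded > mv[k] & discarded < mv[k + 1])
  }, logical(1))
  ibi_pair(diff(mv)[keep] / rate_hz, diff(nv)[keep] / rate_hz,
           kept_index = which(keep))
}
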