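# Agreement and group-effect evaluation of instantaneous heart rate.

#' Convert inter-beat intervals to instantaneous heart rate
#'
#' @param ibi inter-beat interval(s) in seconds, all positive.
#' @return instantaneous heart rate(s) in bpm (`60 / ibi`).
#' @examples
#' ibi_to_ihr(c(1, 0.5, 0.75))  # 60, 120, 80 bpm
#' @export
ibi_to_ihr <- function(ibi) {
  if (any(!is.finite(ibi)) || any(ibi <= 0))
    stop("inter-beat intervals must be positive and finite")
  60 / ibi
}

#' Bland-Altman agreement between ECG and SV instantaneous heart rate
#'
#' Differences are oriented `ihr_ecg - ihr_sv`, so SV overestimation shows as
#' a negative bias. Bias is the mean difference, `sd` the sample standard
#' deviation (n-1), and the limits of agreement are `bias +- 1.96 sd`.
#'
#' @param ihr_ecg,ihr_sv equal-length paired IHR series (bpm), length >= 2.
#' @return object of class `bland_altman`: `bias`, `sd`, `loa_low`,
#'   `loa_high`, `n`, plus the per-pair `means` and `diffs` for plotting.
#' @export
bland_altman <- function(ihr_ecg, ihr_sv) {
  if (length(ihr_ecg) != length(ihr_sv))
    stop("paired series must have equal length")
  if (length(ihr_ecg) < 2) stop("need at least 2 pairs")
  d <- ihr_ecg - ihr_sv
  bias <- mean(d)
  s <- stats::sd(d)
  structure(list(bias = bias, sd = s,
                 loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
                 n = length(d),
                 means = (ihr_ecg + ihr_sv) / 2, diffs = d),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, digits = 4, ...) {
  cat(sprintf("Bland-Altman agreement (n = %d)\n", x$n))
  cat(sprintf("  bias %s bpm, SD %s bpm\n",
              format(x$bias, digits = digits), format(x$sd, digits = digits)))
  cat(sprintf("  LOA [%s, %s] bpm\n",
              format(x$loa_low, digits = digits),
              format(x$loa_high, digits = digits)))
  invisible(x)
}

#' @rdname bland_altman
#' @param x a `bland_altman` object.
#' @param ... passed to [graphics::plot()].
#' @export
plot.bland_altman <- function(x, ...) {
  graphics::plot(x$means, x$diffs,
                 xlab = "mean of ECG and SV IHR (bpm)",
                 ylab = "ECG - SV IHR (bpm)",
                 main = "Bland-Altman", ...)
  graphics::abline(h = x$bias, lty = 1)
  graphics::abline(h = c(x$loa_low, x$loa_high), lty = 2)
  invisible(x)
}

#' Group-effect tests on per-measurement IHR error summaries
#'
#' Takes per-group lists of per-measurement summaries (e.g. the mean absolute
#' IHR difference of each measurement) and reports: a Shapiro-Wilk normality
#' p-value per group (gate at 0.05), the Kruskal-Wallis H test across all
#' groups (distribution-free, suited to a gender-style comparison), and
#' Welch's t-test for the first two groups (unequal variances/sizes, suited
#' to an imbalanced BMI-style split).
#'
#' @param groups named list of numeric vectors, each of length >= 3 (the
#'   Shapiro-Wilk minimum); at least 2 groups.
#' @param alpha significance level used for the reported normality gate
#'   (default 0.05).
#' @return object of class `sv_group_tests`: data frame `shapiro`
#'   (group, W, p, normal), list `kruskal` (`H`, `df`, `p`), list `welch`
#'   (`t`, `df`, `p`; `NULL` unless there are exactly 2 groups).
#' @export
group_tests <- function(groups, alpha = 0.05) {
  if (!is.list(groups) || length(groups) < 2)
    stop("'groups' must be a list of at least 2 numeric vectors")
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 3))
    stop("each group needs at least 3 values for the Shapiro-Wilk test")
  sw <- lapply(groups, function(g) stats::shapiro.test(g))
  shapiro <- data.frame(group = names(groups),
                        W = vapply(sw, function(s) unname(s$statistic), 0),
                        p = vapply(sw, function(s) s$p.value, 0),
                        row.names = NULL)
  shapiro$normal <- shapiro$p > alpha
  values <- unlist(groups, use.names = FALSE)
  fac <- factor(rep(names(groups), sizes), levels = names(groups))
  kw <- stats::kruskal.test(values, fac)
  welch <- NULL
  if (length(groups) == 2) {
    wt <- stats::t.test(groups[[1]], groups[[2]], var.equal = FALSE)
    welch <- list(t = unname(wt$statistic), df = unname(wt$parameter),
                  p = wt$p.value)
  }
  structure(list(shapiro = shapiro,
                 kruskal = list(H = unname(kw$statistic),
                                df = unname(kw$parameter), p = kw$p.value),
                 welch = welch, alpha = alpha),
            class = "sv_group_tests")
}

#' @export
print.sv_group_tests <- function(x, ...) {
  cat("Shapiro-Wilk normality (gate at p >", x$alpha, "):\n")
  print(x$shapiro, row.names = FALSE)
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
              x$kruskal$H, x$kruskal$df, x$kruskal$p))
  if (!is.null(x$welch))
    cat(sprintf("Welch t-test:   t = %.4g, df = %.4g, p = %.4g\n",
                x$welch$t, x$welch$df, x$welch$p))
  invisible(x)
}

#' Ensemble-average the SV cardiac waveform over detected beats
#'
#' Extracts fixed-length windows (one median inter-beat interval, centered on
#' each detected peak) from the displacement series, drops windows that
#' exceed the record bounds, and averages. Both axes are normalized for
#' display: time to `[0, 1]`, amplitude min-max to `[0, 1]` (arbitrary
#' units).
#'
#' @param dr displacement (or principal) series.
#' @param beats a [beat_series()] whose sample indices refer to `dr` at
#'   `rate_hz`, with at least 2 beats.
#' @param rate_hz sampling rate of `dr`.
#' @return list with `time` (normalized), `waveform` (normalized mean beat),
#'   `n_beats` (windows averaged).
#' @export
ensemble_average <- function(dr, beats, rate_hz) {
  pk <- if (inherits(beats, "beat_series")) beats$peaks else as.numeric(beats)
  if (length(pk) < 2) stop("need at least 2 beats to ensemble average")
  idx <- round(pk) + 1L  # 0-based samples -> 1-based positions in dr
  L <- round(stats::median(diff(idx)))
  L <- max(3L, 2L * (L %/% 2L) + 1L)  # odd window length
  half <- (L - 1L) %/% 2L
  ok <- idx - half >= 1L & idx + half <= length(dr)
  if (!any(ok)) stop("no beat window fits inside the record")
  w <- vapply(idx[ok], function(i) dr[(i - half):(i + half)], numeric(L))
  avg <- rowMeans(w)
  rng <- range(avg)
  if (diff(rng) > 0) avg <- (avg - rng[1]) / diff(rng)
  list(time = seq(0, 1, length.out = L), waveform = avg, n_beats = sum(ok))
}
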