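# Independent oracles and fixture builders used across the suite.

# Brute-force circular cross-correlation argmax (spatial-domain loops),
# the integer-resolution oracle for the FFT registration path.
brute_force_shift <- function(ref, mov) {
  d <- dim(ref)
  best <- -Inf
  best_uv <- c(0, 0)
  for (uy in 0:(d[1] - 1)) {
    for (ux in 0:(d[2] - 1)) {
      # correlate mov against ref circularly shifted by (uy, ux)
      rs <- ref[((seq_len(d[1]) - 1 - uy) %% d[1]) + 1,
                ((seq_len(d[2]) - 1 - ux) %% d[2]) + 1]
      v <- sum(mov * rs)
      if (v > best) {
        best <- v
        best_uv <- c(ux, uy)
      }
    }
  }
  s <- best_uv
  if (s[1] > d[2] / 2) s[1] <- s[1] - d[2]
  if (s[2] > d[1] / 2) s[2] <- s[2] - d[1]
  c(dx = s[1], dy = s[2])
}

# circular integer roll of a matrix: pattern moves +sx columns, +sy rows
roll_frame <- function(f, sx, sy) {
  d <- dim(f)
  f[((seq_len(d[1]) - 1 - sy) %% d[1]) + 1,
    ((seq_len(d[2]) - 1 - sx) %% d[2]) + 1]
}

# Validate a matcher result decision-by-decision against the published
# pairing rules, re-deriving every interval from the full ECG list.
# Returns NULL if consistent, otherwise a message describing the first
# violation.
check_matching <- function(m, n, res) {
  J <- length(m)
  exp_m <- numeric(0)
  exp_n <- numeric(0)
  taken <- numeric(0)
  for (j in seq_len(J)) {
    lo <- if (j == 1) 0 else m[j] - 0.4 * (m[j] - m[j - 1])
    hi <- if (j == J) m[j] else m[j] + 0.4 * (m[j + 1] - m[j])
    if (j == 1) hi <- m[1] + 0.4 * (m[2] - m[1])
    inside <- n[n >= lo & n <= hi]
    if (length(inside) == 0) next
    dist <- abs(inside - m[j])
    nearest <- min(inside[dist == min(dist)])  # tie -> earlier peak
    if (nearest %in% taken) next
    taken <- c(taken, nearest)
    exp_m <- c(exp_m, m[j])
    exp_n <- c(exp_n, nearest)
    # every accepted pair must lie inside its interval
    if (nearest < lo || nearest > hi) return(sprintf("pair %d outside interval", j))
  }
  if (!isTRUE(all.equal(exp_m, res$m_valid))) return("m_valid mismatch")
  if (!isTRUE(all.equal(exp_n, res$n_valid))) return("n_valid mismatch")
  NULL
}

# Independent re-derivation of the false-interval exclusion decisions.
check_ibi_selection <- function(all_m, res_matched, res_ibis, rate) {
  mv <- res_matched$m_valid
  if (length(mv) < 2) {
    if (length(res_ibis$ibi_ecg) != 0) return("expected empty IBI lists")
    return(NULL)
  }
  dropped <- all_m[!(all_m %in% mv)]
  exp_keep <- logical(length(mv) - 1)
  for (k in seq_along(exp_keep)) {
    exp_keep[k] <- !any(dropped > mv[k] & dropped < mv[k + 1])
  }
  if (!identical(which(exp_keep), as.integer(res_ibis$kept_index)))
    return("kept_index mismatch")
  if (!isTRUE(all.equal(diff(mv)[exp_keep] / rate, res_ibis$ibi_ecg)))
    return("ibi_ecg mismatch")
  if (!isTRUE(all.equal(diff(res_matched$n_valid)[exp_keep] / rate,
                        res_ibis$ibi_sv)))
    return("ibi_sv mismatch")
  NULL
}

# random peak-set instance: jittered ECG grid plus an SV list with dropouts,
# false positives and timing noise
random_match_instance <- function() {
  n_beats <- sample(5:30, 1)
  m <- cumsum(round(runif(n_beats, 150, 400)))
  jitter <- round(rnorm(n_beats, 0, 15))
  n <- m + jitter
  n <- n[runif(n_beats) > 0.2]                      # dropouts
  extra <- round(runif(sample(0:5, 1), min(m), max(m)))  # false positives
  n <- sort(unique(c(n, extra)))
  list(m = m, n = n)
}

# train of raised-cosine pulses (width_s wide, unit amplitude) at given
# center times, sampled at rate_hz over duration_s
pulse_train <- function(centers_s, duration_s, rate_hz, width_s = 0.3,
                        amps = rep(1, length(centers_s))) {
  t <- (0:(duration_s * rate_hz - 1)) / rate_hz
  x <- numeric(length(t))
  for (i in seq_along(centers_s)) {
    sel <- abs(t - centers_s[i]) < width_s / 2
    x[sel] <- x[sel] + amps[i] * 0.5 *
      (1 + cos(2 * pi * (t[sel] - centers_s[i]) / width_s))
  }
  x
}

# full width at half maximum of the central autocovariance lobe of a frame,
# measured along the column axis
autocorr_fwhm <- function(frame) {
  f <- frame - mean(frame)
  ac <- Re(fft(Mod(fft(f))^2, inverse = TRUE)) / length(f)
  row <- ac[1, ] / ac[1, 1]
  half <- which(row[1:(length(row) / 2)] < 0.5)[1] - 1
  2 * half
}
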