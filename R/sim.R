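# Physics-based synthetic recordings: a fully developed speckle pattern
# translating under a cardiac + respiratory surface-tilt waveform (rendered
# through the near-focused geometry), paired with an ECG whose R-peak times
# are exact ground truth.

# run expr with a temporary RNG state seeded by `seed`, restoring afterwards
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Simulation configuration
#'
#' Defaults describe one synthetic recording: 300 frames/s video and 300 Hz
#' single-lead ECG over `duration_s` seconds, a speckle pattern of
#' correlation length `grain_px`, heart rate `mean_hr_bpm` with Gaussian RR
#' variability `sdnn_s` and respiratory sinus arrhythmia depth `rsa_depth`,
#' and surface tilt composed of a respiratory sinusoid plus one biphasic
#' cardiac pulse per beat. `damping` in (0, 1] scales the cardiac tilt
#' (textile attenuation as a single scalar); `noise_sd` is additive sensor
#' noise as a fraction of the mean intensity.
#'
#' @param duration_s recording length (s).
#' @param frame_rate_hz video frame rate (default 300).
#' @param ecg_rate_hz ECG sampling rate (default 300).
#' @param frame_shape frame size in pixels (default `c(64, 64)`).
#' @param grain_px speckle correlation length (pixels, default 4).
#' @param geometry an [geometry()].
#' @param mean_hr_bpm mean heart rate (default 60).
#' @param sdnn_s RR variability scale (s, default 0.03).
#' @param rsa_depth fractional respiratory modulation of RR (default 0.05).
#' @param resp_rate_hz respiratory rate (default 0.25).
#' @param cardiac_tilt_amp_rad per-beat peak surface tilt (rad, default 1e-6,
#'   about one pixel of speckle shift under the default geometry).
#' @param resp_tilt_amp_rad respiratory baseline tilt amplitude (rad).
#' @param noise_sd additive Gaussian sensor noise, fraction of mean intensity.
#' @param damping cardiac amplitude attenuation in (0, 1].
#' @param shift_axis_deg direction of the speckle motion axis (degrees from
#'   the x axis).
#' @param ecg_noise_sd baseline ECG noise (fraction of R amplitude).
#' @param seed RNG seed for the whole recording.
#' @return a list of class `sv_sim_config`.
#' @export
sim_config <- function(duration_s = 60, frame_rate_hz = 300, ecg_rate_hz = 300,
                       frame_shape = c(64L, 64L), grain_px = 4,
                       geometry = svihr::geometry(),
                       mean_hr_bpm = 60, sdnn_s = 0.03, rsa_depth = 0.05,
                       resp_rate_hz = 0.25, cardiac_tilt_amp_rad = 1e-6,
                       resp_tilt_amp_rad = 5e-6, noise_sd = 0.02,
                       damping = 1, shift_axis_deg = 30,
                       ecg_noise_sd = 0.01, seed = 1L) {
  if (damping <= 0 || damping > 1) stop("'damping' must be in (0, 1]")
  pos <- c(duration_s, frame_rate_hz, ecg_rate_hz, grain_px, resp_rate_hz)
  if (any(pos <= 0)) stop("durations, rates and grain must be positive")
  if (any(c(sdnn_s, rsa_depth, cardiac_tilt_amp_rad, resp_tilt_amp_rad,
            noise_sd, ecg_noise_sd) < 0))
    stop("amplitudes and noise levels must be non-negative")
  structure(list(duration_s = duration_s, frame_rate_hz = frame_rate_hz,
                 ecg_rate_hz = ecg_rate_hz, frame_shape = as.integer(frame_shape),
                 grain_px = grain_px, geometry = geometry,
                 mean_hr_bpm = mean_hr_bpm, sdnn_s = sdnn_s,
                 rsa_depth = rsa_depth, resp_rate_hz = resp_rate_hz,
                 cardiac_tilt_amp_rad = cardiac_tilt_amp_rad,
                 resp_tilt_amp_rad = resp_tilt_amp_rad, noise_sd = noise_sd,
                 damping = damping, shift_axis_deg = shift_axis_deg,
                 ecg_noise_sd = ecg_noise_sd, seed = as.integer(seed)),
            class = "sv_sim_config")
}

#' Generate one fully developed speckle frame
#'
#' Draws a circular complex-Gaussian random field band-limited to correlation
#' length `grain_px` (a disk pupil in the frequency domain filled with
#' independent complex Gaussians) and returns its intensity (squared
#' magnitude) normalized to mean 1. The intensity of such a field follows an
#' exponential distribution, i.e. contrast (sd/mean) equal to 1 — the
#' statistical signature of fully developed speckle.
#'
#' @param shape 2-element frame size (rows, cols).
#' @param grain_px speckle correlation length in pixels (>= 1, at most
#'   `min(shape)/4`).
#' @param seed RNG seed (same seed, same frame).
#' @return numeric matrix of non-negative intensities with mean 1.
#' @export
generate_speckle_frame <- function(shape, grain_px = 4, seed = 1L) {
  shape <- as.integer(shape)
  if (grain_px < 1) stop("'grain_px' must be >= 1")
  if (grain_px > min(shape) / 4)
    stop("'grain_px' larger than min(shape)/4 leaves too few speckle modes")
  with_seed(seed, {
    fr <- fft_freq_idx(shape[1]) / (shape[1] / (2 * grain_px))
    fc <- fft_freq_idx(shape[2]) / (shape[2] / (2 * grain_px))
    pupil <- outer(fr^2, fc^2, "+") <= 1
    np <- sum(pupil)
    spec <- matrix(0i, shape[1], shape[2])
    spec[pupil] <- complex(real = stats::rnorm(np),
                           imaginary = stats::rnorm(np))
    field <- ifft2(spec)
    I <- Mod(field)^2
    I / mean(I)
  })
}

#' Simulate an RR interval series with respiratory sinus arrhythmia
#'
#' `RR_k = (60 / mean_hr) * (1 + rsa_depth * sin(2 pi resp_rate t_k)) + e_k`
#' with `e_k ~ N(0, sdnn_s)`, clipped to at least 0.3 s, where `t_k` is the
#' cumulative beat time. Intervals are generated until the cumulative times
#' cover `duration_s`.
#'
#' @param cfg an [sim_config()].
#' @return numeric vector of RR intervals (s); `cumsum()` gives beat times.
#' @export
simulate_rr_series <- function(cfg) {
  stopifnot(inherits(cfg, "sv_sim_config"))
  if (cfg$mean_hr_bpm < 30 || cfg$mean_hr_bpm > 200)
    stop("'mean_hr_bpm' outside the physiological range [30, 200]")
  base <- 60 / cfg$mean_hr_bpm
  rr <- numeric(0)
  t <- 0
  while (t < cfg$duration_s) {
    k <- base * (1 + cfg$rsa_depth * sin(2 * pi * cfg$resp_rate_hz * t)) +
      stats::rnorm(1, 0, cfg$sdnn_s)
    k <- max(k, 0.3)
    rr <- c(rr, k)
    t <- t + k
  }
  rr
}

# biphasic cardiac pulse: derivative of a Gaussian, peak magnitude 1,
# truncated to the fixed 120 ms support (+-3 sigma, sigma = 20 ms)
cardiac_pulse <- function(t, sigma = 0.02) {
  out <- numeric(length(t))
  inside <- abs(t) <= 3 * sigma
  out[inside] <- -(t[inside] / sigma) * exp(0.5 - t[inside]^2 / (2 * sigma^2))
  out
}

#' Simulate the surface tilt waveform driven by heartbeat and respiration
#'
#' Sum of a respiratory sinusoid (amplitude `resp_tilt_amp_rad` at
#' `resp_rate_hz`) and one biphasic cardiac pulse (derivative-of-Gaussian,
#' fixed 120 ms support) of amplitude `damping * cardiac_tilt_amp_rad`
#' anchored at each cumulative RR time. The anchor times are the ground-truth
#' SV beat times.
#'
#' @param rr RR interval series (s), e.g. from [simulate_rr_series()].
#' @param cfg an [sim_config()].
#' @return list with `alpha` (tilt in rad, sampled at the frame rate over
#'   `duration_s`) and `beat_times` (anchor times in s within the duration).
#' @export
simulate_tilt_waveform <- function(rr, cfg) {
  stopifnot(inherits(cfg, "sv_sim_config"))
  if (!length(rr)) stop("'rr' must be nonempty")
  nf <- round(cfg$duration_s * cfg$frame_rate_hz)
  t <- (0:(nf - 1)) / cfg$frame_rate_hz
  alpha <- cfg$resp_tilt_amp_rad * sin(2 * pi * cfg$resp_rate_hz * t)
  amp <- cfg$damping * cfg$cardiac_tilt_amp_rad
  beat_times <- cumsum(rr)
  beat_times <- beat_times[beat_times < cfg$duration_s]
  for (tk in beat_times) alpha <- alpha + amp * cardiac_pulse(t - tk)
  list(alpha = alpha, beat_times = beat_times)
}

#' Render a speckle video from a tilt waveform
#'
#' Frame `t` is the base speckle pattern translated by
#' `s(t) = K * tan(alpha(t)) / pixel_pitch` pixels along a fixed motion axis
#' (`shift_axis_deg`), using exact spectral phase-ramp shifting with periodic
#' boundary, plus additive Gaussian sensor noise of sd
#' `noise_sd * mean(base)` (clipped at zero). Uses the current RNG state for
#' the noise; [simulate_sv_recording()] seeds it.
#'
#' @param base base frame from [generate_speckle_frame()].
#' @param tilt tilt series in radians (one value per frame).
#' @param geom an [geometry()].
#' @param cfg an [sim_config()].
#' @return a [frame_stack()] at `cfg$frame_rate_hz`.
#' @export
render_video <- function(base, tilt, geom = geometry(), cfg = sim_config()) {
  d <- dim(base)
  s <- tilt_to_shift(tilt, geom)
  if (max(abs(s)) > min(d) / 4)
    stop(sprintf("peak speckle shift %.2f px exceeds frame size/4; wraparound would dominate",
                 max(abs(s))))
  th <- cfg$shift_axis_deg * pi / 180
  sx <- s * cos(th); sy <- s * sin(th)
  Fb <- fft(base)
  fr <- fft_freq_idx(d[1]) / d[1]
  fc <- fft_freq_idx(d[2]) / d[2]
  nsd <- cfg$noise_sd * mean(base)
  frames <- array(0, c(d, length(tilt)))
  for (k in seq_along(tilt)) {
    ramp <- exp(-2i * pi * sy[k] * fr) %o% exp(-2i * pi * sx[k] * fc)
    f <- Re(ifft2(Fb * ramp))
    if (nsd > 0) f <- f + stats::rnorm(length(f), 0, nsd)
    frames[, , k] <- pmax(f, 0)
  }
  frame_stack(frames, rate_hz = cfg$frame_rate_hz)
}

# PQRST-like template: Gaussian bumps; dominant narrow R wave at offset 0
ecg_template <- function(t) {
  g <- function(mu, sd, a) a * exp(-(t - mu)^2 / (2 * sd^2))
  g(-0.16, 0.020, 0.12) + g(-0.030, 0.006, -0.10) + g(0, 0.008, 1) +
    g(0.030, 0.007, -0.15) + g(0.22, 0.040, 0.25)
}

#' Synthesize a single-lead ECG with known R-peak positions
#'
#' Places a fixed PQRST-like template (dominant narrow R wave) at each
#' cumulative RR time on a flat baseline with additive Gaussian noise. The
#' returned beat series holds the exact R sample indices.
#'
#' @param rr RR interval series (s).
#' @param rate_hz sampling rate (default 300).
#' @param noise_sd baseline noise sd as a fraction of the R amplitude.
#' @param duration_s record length; defaults to `sum(rr)` plus half a second.
#' @return list with `ecg` (an [ecg_record()]) and `beats` (a [beat_series()]
#'   of exact R sample indices).
#' @export
synthesize_ecg <- function(rr, rate_hz = 300, noise_sd = 0.01,
                           duration_s = NULL) {
  if (!length(rr)) stop("'rr' must be nonempty")
  if (sum(rr) < 0.6) stop("total RR time shorter than one PQRST template")
  if (is.null(duration_s)) duration_s <- sum(rr) + 0.5
  n <- round(duration_s * rate_hz)
  tt <- (0:(n - 1)) / rate_hz
  x <- numeric(n)
  beat_times <- cumsum(rr)
  beat_times <- beat_times[beat_times < duration_s - 0.3]
  r_idx <- round(beat_times * rate_hz)
  for (k in r_idx) {
    sel <- max(0, k - round(0.3 * rate_hz)):min(n - 1, k + round(0.35 * rate_hz))
    x[sel + 1] <- x[sel + 1] + ecg_template(tt[sel + 1] - k / rate_hz)
  }
  if (noise_sd > 0) x <- x + stats::rnorm(n, 0, noise_sd)
  list(ecg = ecg_record(x, rate_hz = rate_hz),
       beats = beat_series(r_idx, modality = "ECG", rate_hz = rate_hz))
}

#' Simulate one paired SV + ECG recording with ground truth
#'
#' Runs the full generative chain under a single seed: RR series with
#' respiratory sinus arrhythmia, cardiac + respiratory tilt waveform,
#' speckle video rendered through the near-focused geometry, and a paired
#' ECG. Identical configurations (including the seed) give bit-identical
#' output.
#'
#' @param cfg an [sim_config()].
#' @return list with `frames` (a [frame_stack()]), `ecg` (an [ecg_record()]),
#'   and `truth`: `rr` (intervals), `sv_beats` and `r_peaks`
#'   ([beat_series()] of ground-truth positions).
#' @export
simulate_sv_recording <- function(cfg = sim_config()) {
  stopifnot(inherits(cfg, "sv_sim_config"))
  with_seed(cfg$seed, {
    rr <- simulate_rr_series(cfg)
    tw <- simulate_tilt_waveform(rr, cfg)
    base <- generate_speckle_frame(cfg$frame_shape, cfg$grain_px,
                                   seed = cfg$seed + 1L)
    frames <- render_video(base, tw$alpha, cfg$geometry, cfg)
    syn <- synthesize_ecg(rr, rate_hz = cfg$ecg_rate_hz,
                          noise_sd = cfg$ecg_noise_sd,
                          duration_s = cfg$duration_s)
    list(frames = frames, ecg = syn$ecg,
         truth = list(rr = rr,
                      sv_beats = beat_series(round(tw$beat_times *
                                                     cfg$frame_rate_hz),
                                             modality = "SV",
                                             rate_hz = cfg$frame_rate_hz),
                      r_peaks = syn$beats))
  })
}

#' Build a simulation configuration from a pipeline configuration
#'
#' Combines the `simulation` and `geometry` sections of an [sv_config()] /
#' [read_sv_config()] list into an [sim_config()].
#'
#' @param config an `sv_config` list.
#' @return an `sv_sim_config`.
#' @export
as_sim_config <- function(config) {
  g <- config$geometry
  geom <- geometry(L1 = g$L1, L2 = g$L2, F_len = g$F_len,
                   pixel_pitch = g$pixel_pitch, K = g$K)
  s <- config$simulation
  args <- s[intersect(names(s), names(formals(sim_config)))]
  args$geometry <- geom
  do.call(sim_config, args)
}
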