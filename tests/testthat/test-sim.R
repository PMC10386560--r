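test_that("speckle frames are deterministic, mean-1, fully developed", {
  f1 <- generate_speckle_frame(c(256, 256), 4, seed = 3)
  f2 <- generate_speckle_frame(c(256, 256), 4, seed = 3)
  expect_identical(f1, f2)
  expect_equal(mean(f1), 1)
  # exponential-intensity law: contrast (sd/mean) = 1
  expect_equal(sd(f1) / mean(f1), 1, tolerance = 0.05)
  # intensity histogram consistent with the exponential distribution
  ks <- suppressWarnings(stats::ks.test(as.vector(f1), "pexp", 1))
  expect_lt(unname(ks$statistic), 0.02)
  expect_error(generate_speckle_frame(c(16, 16), 8), "grain_px")
})

test_that("speckle correlation length grows with grain size", {
  f2 <- generate_speckle_frame(c(256, 256), 2, seed = 5)
  f8 <- generate_speckle_frame(c(256, 256), 8, seed = 5)
  expect_gt(autocorr_fwhm(f8), autocorr_fwhm(f2))
})

test_that("RR series has the configured mean, variability and RSA", {
  cfg0 <- sim_config(duration_s = 30, mean_hr_bpm = 60, sdnn_s = 0,
                     rsa_depth = 0)
  rr0 <- simulate_rr_series(cfg0)
  expect_true(all(rr0 == 1))

  cfg <- sim_config(duration_s = 300, mean_hr_bpm = 70, sdnn_s = 0.03,
                    rsa_depth = 0, seed = 9)
  rr <- svihr:::with_seed(9, simulate_rr_series(cfg))
  se <- 0.03 / sqrt(length(rr))
  expect_lt(abs(mean(rr) - 60 / 70), 3 * se)

  # RSA: spectrum of the interpolated RR series peaks at the breathing rate
  cfg2 <- sim_config(duration_s = 300, mean_hr_bpm = 60, sdnn_s = 0,
                     rsa_depth = 0.1, resp_rate_hz = 0.25)
  rr2 <- svihr:::with_seed(9, simulate_rr_series(cfg2))
  tk <- cumsum(rr2)
  g <- seq(5, 295, by = 0.25)
  u <- stats::approx(tk, rr2, xout = g)$y
  sp <- stats::spec.pgram(u - mean(u), plot = FALSE, taper = 0)
  fpk <- sp$freq[which.max(sp$spec)] * 4  # grid rate 4 Hz
  expect_equal(fpk, 0.25, tolerance = 0.02)

  expect_error(simulate_rr_series(sim_config(mean_hr_bpm = 20)),
               "physiological range")
})

test_that("tilt waveform composes respiration and per-beat cardiac pulses", {
  cfg <- sim_config(duration_s = 4, cardiac_tilt_amp_rad = 0,
                    resp_tilt_amp_rad = 2e-5, resp_rate_hz = 0.25)
  tw <- simulate_tilt_waveform(c(1, 1, 1), cfg)
  t <- (0:(length(tw$alpha) - 1)) / cfg$frame_rate_hz
  expect_equal(tw$alpha, 2e-5 * sin(2 * pi * 0.25 * t))

  # one beat, no respiration: one pulse, zero outside the 120 ms support
  cfg2 <- sim_config(duration_s = 4, cardiac_tilt_amp_rad = 1e-6,
                     resp_tilt_amp_rad = 0)
  tw2 <- simulate_tilt_waveform(2, cfg2)
  expect_equal(tw2$beat_times, 2)
  outside <- abs(t - 2) > 0.06
  expect_true(all(tw2$alpha[outside] == 0))
  expect_gt(max(abs(tw2$alpha)), 0)

  # damping scales the cardiac component linearly
  twd <- simulate_tilt_waveform(2, sim_config(duration_s = 4,
                                              resp_tilt_amp_rad = 0,
                                              damping = 0.5))
  twf <- simulate_tilt_waveform(2, sim_config(duration_s = 4,
                                              resp_tilt_amp_rad = 0,
                                              damping = 1))
  expect_equal(twd$alpha, 0.5 * twf$alpha)
})

test_that("rendered video translates the base pattern per the geometry", {
  base <- generate_speckle_frame(c(64, 64), 4, seed = 1)
  geom <- geometry()
  cfg <- sim_config(duration_s = 4, noise_sd = 0, shift_axis_deg = 30)

  # zero tilt, zero noise: every frame is the base frame
  still <- render_video(base, rep(0, 5), geom, cfg)
  for (k in 1:5) expect_equal(still$frames[, , k], base, tolerance = 1e-12)

  # unit consistency: tan(alpha) = pixel_pitch / K gives a 1.0 px shift
  a1 <- atan(geom$pixel_pitch / geom$K)
  mv <- render_video(base, c(0, a1, a1), geom, cfg)
  s <- register_pair(base, mv$frames[, , 2], upsampling = 100)
  expect_equal(sqrt(sum(s^2)), 1, tolerance = 0.01)
  expect_equal(unname(s["dy"] / s["dx"]), tan(30 * pi / 180), tolerance = 0.05)

  # excessive shift is refused
  expect_error(render_video(base, rep(0.1, 3), geom, cfg), "wraparound")
})

test_that("synthetic ECG places exact R peaks on the RR grid", {
  syn <- synthesize_ecg(rep(1, 60), rate_hz = 300, noise_sd = 0)
  expect_equal(syn$beats$peaks, 300 * (1:60))
  # noise-free: the global maximum of each beat is the exported R index
  x <- syn$ecg$samples
  for (r in syn$beats$peaks[c(1, 30, 60)]) {
    w <- (r - 90):(r + 90) + 1
    expect_equal(w[which.max(x[w])] - 1, r)
  }
  expect_error(synthesize_ecg(numeric(0)), "nonempty")
  expect_error(synthesize_ecg(0.2), "shorter than one")
})

test_that("a full simulated recording is deterministic under its seed", {
  cfg <- sim_config(duration_s = 5, frame_shape = c(32L, 32L), seed = 21L)
  r1 <- simulate_sv_recording(cfg)
  r2 <- simulate_sv_recording(cfg)
  expect_identical(r1$frames$frames, r2$frames$frames)
  expect_identical(r1$ecg$samples, r2$ecg$samples)
  expect_identical(r1$truth, r2$truth)

  # ground-truth closure: beat times strictly increasing, inside the duration
  for (b in list(r1$truth$sv_beats, r1$truth$r_peaks)) {
    tt <- peak_times(b)
    expect_false(is.unsorted(tt, strictly = TRUE))
    expect_true(all(tt >= 0 & tt <= cfg$duration_s))
  }
})
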