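test_that("principal signal demodulates an amplitude-modulated carrier", {
  cfg <- detector_config()
  fs <- 300
  t <- (0:(40 * fs - 1)) / fs

  expect_equal(principal_signal(rep(0, 40 * fs), fs, cfg), rep(0, 40 * fs))

  # 20 Hz carrier, 1 Hz modulation at depth 0.5: envelope band-pass leaves
  # ~0.5 cos(2 pi t) after transients
  x <- (1 + 0.5 * cos(2 * pi * 1 * t)) * cos(2 * pi * 20 * t)
  ps <- principal_signal(x, fs, cfg)
  expect_equal(length(ps), length(x))
  mid <- ps[(5 * fs):(35 * fs)]
  ref <- 0.5 * cos(2 * pi * 1 * t[(5 * fs):(35 * fs)])
  expect_gt(cor(mid, ref), 0.99)
  expect_equal(sqrt(2) * sd(mid), 0.5, tolerance = 0.05)
  sp <- stats::spec.pgram(mid, plot = FALSE, taper = 0)
  expect_equal(sp$freq[which.max(sp$spec)] * fs, 1, tolerance = 0.05)

  expect_error(principal_signal(rnorm(10), fs, cfg), "too short")
})

test_that("SV peak detector finds pulse trains and rejects sub-threshold pulses", {
  fs <- 100
  cfg <- detector_config()
  expect_length(detect_sv_peaks(rep(0, 60 * fs), fs, cfg)$peaks, 0)

  centers <- 0.5 + 0:59
  x <- pulse_train(centers, 60, fs)
  pk <- detect_sv_peaks(x, fs, cfg)$peaks
  expect_length(pk, 60)
  expect_true(all(abs(pk - centers * fs) <= 1))

  # one pulse at 10% amplitude falls below thresh_frac x level
  amps <- rep(1, 60); amps[30] <- 0.1
  x2 <- pulse_train(centers, 60, fs, amps = amps)
  pk2 <- detect_sv_peaks(x2, fs, cfg)$peaks
  expect_length(pk2, 59)
  expect_false(any(abs(pk2 - centers[30] * fs) <= 2))
})

test_that("peak detectors are invariant to positive rescaling", {
  fs <- 100
  set.seed(3)
  x <- pulse_train(0.5 + 0:29, 30, fs, amps = runif(30, 0.6, 1)) +
    rnorm(30 * fs, 0, 0.02)
  p1 <- detect_sv_peaks(x, fs)$peaks
  p2 <- detect_sv_peaks(37.5 * x, fs)$peaks
  expect_identical(p1, p2)

  syn <- svihr:::with_seed(5, synthesize_ecg(rep(c(0.8, 1.0), 15), 300,
                                             noise_sd = 0.01))
  r1 <- detect_r_peaks(syn$ecg)$peaks
  r2 <- detect_r_peaks(ecg_record(syn$ecg$samples * 0.013, 300))$peaks
  expect_identical(r1, r2)
})

test_that("detected peaks respect the refractory spacing", {
  fs <- 100
  set.seed(6)
  x <- pulse_train(0.5 + 0:29, 30, fs) + rnorm(30 * fs, 0, 0.1)
  cfg <- detector_config()
  pk <- detect_sv_peaks(x, fs, cfg)$peaks
  expect_true(all(diff(pk) >= cfg$refractory_s * fs))

  syn <- svihr:::with_seed(7, synthesize_ecg(rep(1, 30), 300, noise_sd = 0.03))
  rp <- detect_r_peaks(syn$ecg)$peaks
  expect_true(all(diff(rp) >= 0.2 * 300))
})

test_that("R-peak detector recovers synthetic ECG timing", {
  expect_warning(detect_r_peaks(ecg_record(rep(0.3, 3000), 300)), "flat|no R")

  syn <- svihr:::with_seed(11, synthesize_ecg(rep(1, 60), 300, noise_sd = 0.01))
  det <- detect_r_peaks(syn$ecg)
  expect_length(det$peaks, 60)
  nearest <- vapply(syn$beats$peaks,
                    function(b) min(abs(det$peaks - b)), 0)
  expect_true(all(nearest <= 3))  # 10 ms at 300 Hz

  # alternating 0.8/1.2 s rhythm is recovered interval by interval
  rr <- rep(c(0.8, 1.2), 30)
  syn2 <- svihr:::with_seed(13, synthesize_ecg(rr, 300, noise_sd = 0.01))
  det2 <- detect_r_peaks(syn2$ecg)
  expect_length(det2$peaks, length(syn2$beats$peaks))
  rec_rr <- diff(det2$peaks) / 300
  expect_true(all(abs(rec_rr - rr[2:length(syn2$beats$peaks)]) <= 0.010))

  # off-rate input is resampled internally
  syn3 <- svihr:::with_seed(15, synthesize_ecg(rep(1, 20), 250, noise_sd = 0.01))
  det3 <- detect_r_peaks(syn3$ecg)
  expect_equal(det3$rate_hz, 300)
  expect_length(det3$peaks, 20)
})
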