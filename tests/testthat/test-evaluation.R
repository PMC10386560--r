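test_that("IBI to IHR conversion", {
  expect_equal(ibi_to_ihr(c(1, 0.5, 0.75)), c(60, 120, 80))
  expect_error(ibi_to_ihr(0), "positive")
  expect_error(ibi_to_ihr(c(1, -0.2)), "positive")
})

test_that("Bland-Altman reproduces the worked example and its symmetries", {
  ba <- bland_altman(c(60, 62, 64), c(61, 61, 65))
  expect_equal(ba$bias, -1 / 3, tolerance = 1e-12)
  expect_equal(ba$sd, 1.1547005, tolerance = 1e-6)
  expect_equal(ba$loa_low, -2.5966, tolerance = 1e-4)
  expect_equal(ba$loa_high, 1.9299, tolerance = 1e-4)
  expect_equal(ba$n, 3)
  expect_equal(ba$loa_low, ba$bias - 1.96 * ba$sd)
  expect_equal(ba$loa_high, ba$bias + 1.96 * ba$sd)

  a <- c(70, 72, 68, 75)
  same <- bland_altman(a, a)
  expect_equal(c(same$bias, same$sd, same$loa_low, same$loa_high),
               c(0, 0, 0, 0))

  # translation invariance and argument-swap antisymmetry
  b <- a + rnorm(4)
  ba1 <- bland_altman(a, b)
  ba2 <- bland_altman(a + 5, b + 5)
  expect_equal(ba1$bias, ba2$bias)
  expect_equal(ba1$sd, ba2$sd)
  sw <- bland_altman(b, a)
  expect_equal(sw$bias, -ba1$bias)
  expect_equal(sw$loa_low, -ba1$loa_high)
  expect_equal(sw$loa_high, -ba1$loa_low)

  expect_error(bland_altman(1:3, 1:4), "equal length")
  expect_error(bland_altman(1, 1), "at least 2")
})

test_that("group tests report Shapiro-Wilk, Kruskal-Wallis and Welch", {
  g1 <- c(1, 2, 3, 4, 5)
  g2 <- c(2, 3, 4, 5, 6)
  gt <- group_tests(list(a = g1, b = g2))
  expect_equal(gt$welch$t, -1, tolerance = 1e-12)
  expect_equal(gt$welch$df, 8, tolerance = 1e-12)
  expect_equal(nrow(gt$shapiro), 2)
  expect_true(all(gt$shapiro$p > 0))

  # identical groups: H = 0 (ties broadcast equally)
  same <- group_tests(list(a = g1, b = g1))
  expect_equal(same$kruskal$H, 0, tolerance = 1e-12)
  expect_equal(same$welch$t, 0, tolerance = 1e-12)

  # three groups: Kruskal-Wallis only, no Welch pair
  gt3 <- group_tests(list(a = g1, b = g2, c = g1 + 3))
  expect_null(gt3$welch)
  expect_equal(gt3$kruskal$df, 2)

  expect_error(group_tests(list(a = g1)), "at least 2")
  expect_error(group_tests(list(a = g1, b = c(1, 2))), "at least 3 values")
})

test_that("ensemble averaging recovers the beat template", {
  fs <- 100
  centers <- 0.5 + 0:19
  x <- pulse_train(centers, 21, fs)
  beats <- beat_series(centers * fs, "SV", fs)
  ens <- ensemble_average(x, beats, fs)
  expect_equal(max(ens$waveform), 1)
  expect_equal(min(ens$waveform), 0)
  expect_equal(range(ens$time), c(0, 1))
  # identical repeated beats: the average equals one normalized beat
  mid <- (length(ens$waveform) + 1) / 2
  expect_equal(which.max(ens$waveform), mid)

  # sqrt(n) law: RMS deviation from the clean template roughly halves
  # when the beat count quadruples
  rms_err <- function(n_beats, seed) {
    set.seed(seed)
    cen <- 0.5 + 0:(n_beats - 1)
    noisy <- pulse_train(cen, n_beats + 1, fs) +
      rnorm((n_beats + 1) * fs, 0, 0.5)
    e <- ensemble_average(noisy, beat_series(cen * fs, "SV", fs), fs)
    clean <- ensemble_average(pulse_train(cen, n_beats + 1, fs),
                              beat_series(cen * fs, "SV", fs), fs)
    L <- min(length(e$waveform), length(clean$waveform))
    sqrt(mean((e$waveform[1:L] - clean$waveform[1:L])^2))
  }
  r16 <- mean(vapply(1:4, function(s) rms_err(16, s), 0))
  r64 <- mean(vapply(1:4, function(s) rms_err(64, s + 10), 0))
  expect_gt(r16 / r64, 1.4)
  expect_lt(r16 / r64, 3.0)

  expect_error(ensemble_average(x, beat_series(50, "SV", fs), fs),
               "at least 2 beats")
})
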