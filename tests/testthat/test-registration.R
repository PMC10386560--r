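test_that("register_pair recovers identity, integer and fractional shifts", {
  f <- generate_speckle_frame(c(64, 64), 4, seed = 2)
  expect_equal(register_pair(f, f, 100), c(dx = 0, dy = 0))

  # integer circular shift: the coarse correlation peak is exact
  mv <- roll_frame(f, 3, -2)
  expect_equal(register_pair(f, mv, 100), c(dx = 3, dy = -2))

  # fractional spectral shift, noise-free
  mv2 <- spectral_shift(f, 0.37, -1.24)
  s <- register_pair(f, mv2, 100)
  expect_lt(abs(s["dx"] - 0.37), 0.01)
  expect_lt(abs(s["dy"] + 1.24), 0.01)

  expect_error(register_pair(f, f[1:32, 1:32], 100), "same shape")
  expect_error(register_pair(matrix(1, 8, 8), matrix(1, 8, 8)),
               "all-constant")
})

test_that("register_pair is anti-symmetric within the upsampling resolution", {
  f <- generate_speckle_frame(c(64, 64), 4, seed = 8)
  set.seed(8)
  for (i in 1:5) {
    sx <- runif(1, -2, 2); sy <- runif(1, -2, 2)
    mv <- spectral_shift(f, sx, sy)
    a <- register_pair(f, mv, 100)
    b <- register_pair(mv, f, 100)
    expect_lt(max(abs(a + b)), 1 / 100 + 1e-12)
  }
})

test_that("upsampling 1 equals the brute-force cross-correlation argmax", {
  set.seed(4)
  f <- generate_speckle_frame(c(16, 16), 2, seed = 4)
  for (i in 1:8) {
    sx <- sample(-6:6, 1); sy <- sample(-6:6, 1)
    mv <- roll_frame(f, sx, sy) + matrix(rnorm(256, 0, 0.05), 16)
    mv <- pmax(mv, 0)
    expect_equal(register_pair(f, mv, upsampling = 1),
                 brute_force_shift(f, mv))
  }
})

test_that("displacement traces have length n-1 and recover constructed motion", {
  f <- generate_speckle_frame(c(64, 64), 4, seed = 6)
  still <- frame_stack(array(rep(f, 2), c(64, 64, 2)), rate_hz = 300)
  tr0 <- extract_displacement_trace(still, 100)
  expect_equal(tr0$dx, 0)
  expect_equal(tr0$dy, 0)

  frames <- array(0, c(64, 64, 3))
  for (k in 0:2) frames[, , k + 1] <- spectral_shift(f, 0.5 * k, 0)
  tr <- extract_displacement_trace(frame_stack(frames, 300), 100)
  expect_equal(length(tr$dx), 2)
  expect_equal(tr$dx, c(0.5, 0.5), tolerance = 0.02)
  expect_equal(tr$dy, c(0, 0), tolerance = 0.01)

  n <- 7
  frames <- array(0, c(64, 64, n))
  for (k in seq_len(n)) frames[, , k] <- spectral_shift(f, runif(1), runif(1))
  expect_equal(length(extract_displacement_trace(frame_stack(frames, 300), 10)$dx),
               n - 1)
})

test_that("dr is the principal-axis projection, invariant under rotation", {
  set.seed(12)
  s <- as.numeric(arima.sim(list(ar = 0.8), 200))

  # motion purely along x: dr equals dx
  tr <- derive_dr(displacement_trace(dx = s, dy = rep(0, 200), rate_hz = 300))
  expect_equal(tr$dr, s, tolerance = 1e-9)

  # motion at 45 degrees with equal components s/sqrt(2): dr recovers s
  tr45 <- derive_dr(displacement_trace(s / sqrt(2), s / sqrt(2), 300))
  expect_equal(abs(tr45$dr), abs(s), tolerance = 1e-9)

  # common rotation of all shift vectors changes dr by at most a global sign
  th <- 30 * pi / 180
  dxr <- cos(th) * s - sin(th) * 0.3 * rev(s)
  dyr <- sin(th) * s + cos(th) * 0.3 * rev(s)
  base <- derive_dr(displacement_trace(s, 0.3 * rev(s), 300))$dr
  rot <- derive_dr(displacement_trace(dxr, dyr, 300))$dr
  err <- min(max(abs(rot - base)), max(abs(rot + base)))
  expect_lt(err, 1e-9)

  expect_warning(derive_dr(displacement_trace(rep(1, 5), rep(2, 5), 300)),
                 "zero-variance")
  expect_error(derive_dr(displacement_trace(1, 1, 300)), "at least 2")
})

test_that("tilt-to-shift conversion is consistent and linear for small angles", {
  geom <- geometry()
  expect_equal(tilt_to_shift(0, geom), 0)
  expect_equal(tilt_to_shift(atan(geom$pixel_pitch / geom$K), geom), 1)
  eps <- 1e-7
  expect_equal(tilt_to_shift(2 * eps, geom) / tilt_to_shift(eps, geom), 2,
               tolerance = 1e-9)
  expect_error(tilt_to_shift(pi / 2, geom), "pi/2")
})
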