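# Sub-pixel translation registration by upsampled cross-correlation:
# coarse integer peak from the FFT cross-correlation, then a localized
# matrix-multiply DFT upsampled around that peak (resolution 1/upsampling px).

# signed FFT frequency indices 0, 1, ..., -1 for length n
fft_freq_idx <- function(n) {
  k <- 0:(n - 1)
  k[k > n / 2] <- k[k > n / 2] - n
  k
}

ifft2 <- function(x) fft(x, inverse = TRUE) / length(x)

#' Shift an image by a (fractional) translation using the Fourier phase ramp
#'
#' Exact spectral translation with periodic boundary: the returned image `g`
#' satisfies `g(r, c) = f(r - sy, c - sx)` under circular indexing, i.e. the
#' pattern moves by `+sx` columns and `+sy` rows. Used by the simulator to
#' render known sub-pixel motion and by tests as the registration oracle.
#'
#' @param frame numeric matrix.
#' @param sx,sy shift in pixels along columns (x) and rows (y).
#' @return shifted numeric matrix (real part of the inverse transform).
#' @export
spectral_shift <- function(frame, sx, sy) {
  d <- dim(frame)
  fr <- fft_freq_idx(d[1]) / d[1]
  fc <- fft_freq_idx(d[2]) / d[2]
  ramp <- exp(-2i * pi * sy * fr) %o% exp(-2i * pi * sx * fc)
  Re(ifft2(fft(frame) * ramp))
}

# core estimator on precomputed FFTs; returns c(dx, dy)
register_core <- function(F_ref, F_mov, usfac) {
  d <- dim(F_ref)
  P <- F_mov * Conj(F_ref)
  cc <- ifft2(P)
  pk <- arrayInd(which.max(Mod(cc)), d)
  # 0-based, mapped to signed shifts
  ry <- pk[1] - 1L; if (ry > d[1] / 2) ry <- ry - d[1]
  rx <- pk[2] - 1L; if (rx > d[2] / 2) rx <- rx - d[2]
  if (usfac <= 1L) return(c(dx = rx, dy = ry))
  # upsampled DFT on a 1.5 px neighbourhood of the coarse peak
  nr <- ceiling(1.5 * usfac)
  off <- floor(nr / 2)
  ur <- ry + ((0:(nr - 1)) - off) / usfac
  uc <- rx + ((0:(nr - 1)) - off) / usfac
  kr <- exp((2i * pi / d[1]) * outer(ur, fft_freq_idx(d[1])))
  kc <- exp((2i * pi / d[2]) * outer(fft_freq_idx(d[2]), uc))
  ccu <- kr %*% P %*% kc
  pku <- arrayInd(which.max(Mod(ccu)), dim(ccu))
  c(dx = uc[pku[2]], dy = ur[pku[1]])
}

#' Register one frame pair to sub-pixel precision
#'
#' Estimates the translation that maps `ref` onto `mov` by locating the peak
#' of the circular cross-correlation, refined by a localized upsampled
#' discrete Fourier transform around the coarse peak (resolution
#' `1/upsampling` pixels). Convention: positive `dx`/`dy` means the pattern
#' moved toward increasing column/row index.
#'
#' @param ref,mov equal-shape numeric matrices.
#' @param upsampling integer upsampling factor (>= 1, default 100, i.e.
#'   0.01-pixel resolution).
#' @param hann apply a Hann window to both frames before registration
#'   (useful for non-periodic real video edges; off by default).
#' @return named numeric vector `c(dx = , dy = )` in pixels.
#' @export
register_pair <- function(ref, mov, upsampling = 100L, hann = FALSE) {
  if (!identical(dim(ref), dim(mov)))
    stop("'ref' and 'mov' must have the same shape")
  if (upsampling < 1) stop("'upsampling' must be >= 1")
  if (max(ref) == min(ref) || max(mov) == min(mov))
    stop("all-constant frame: correlation peak undefined")
  if (hann) {
    w <- hann_window(dim(ref))
    ref <- ref * w; mov <- mov * w
  }
  register_core(fft(ref), fft(mov), as.integer(upsampling))
}

hann_window <- function(d) {
  wr <- 0.5 - 0.5 * cos(2 * pi * (0:(d[1] - 1)) / (d[1] - 1))
  wc <- 0.5 - 0.5 * cos(2 * pi * (0:(d[2] - 1)) / (d[2] - 1))
  wr %o% wc
}

#' Extract the per-frame-pair displacement trace from a speckle video
#'
#' Registers every consecutive frame pair (k, k+1); element k of the trace is
#' the shift from frame k to frame k+1 and is timestamped at frame k. Frame
#' FFTs are computed once and streamed. The combined series `dr` is left
#' unset; see [derive_dr()].
#'
#' @param stack a [frame_stack()] with at least 2 frames.
#' @param upsampling passed to the pair registration (default 100).
#' @param hann apply a Hann window to each frame first.
#' @return a [displacement_trace()] of length `n_frames - 1`.
#' @export
extract_displacement_trace <- function(stack, upsampling = 100L, hann = FALSE) {
  stopifnot(inherits(stack, "frame_stack"))
  n <- n_frames(stack)
  d <- dim(stack$frames)[1:2]
  w <- if (hann) hann_window(d) else NULL
  dx <- dy <- numeric(n - 1)
  get_fft <- function(k) {
    f <- stack$frames[, , k]
    if (max(f) == min(f))
      stop("all-constant frame ", k, ": correlation peak undefined")
    if (!is.null(w)) f <- f * w
    fft(f)
  }
  F_prev <- get_fft(1)
  for (k in seq_len(n - 1)) {
    F_next <- get_fft(k + 1)
    s <- register_core(F_prev, F_next, as.integer(upsampling))
    dx[k] <- s["dx"]; dy[k] <- s["dy"]
    F_prev <- F_next
  }
  displacement_trace(dx, dy, rate_hz = stack$rate_hz, t0 = stack$t0)
}

#' Reduce two-axis shifts to the orientation-independent series Dr
#'
#' Projects each `(dx, dy)` sample onto the first principal axis of the
#' centered displacement scatter. Because the principal axis co-rotates with
#' the data, the result is invariant (up to one global sign) under any common
#' rotation of all shift vectors, i.e. independent of how the camera is
#' oriented relative to the motion axis. The global sign is fixed so that
#' `dr` correlates non-negatively with `dx` (a tie is broken toward
#' non-negative correlation with `dy`).
#'
#' @param trace a [displacement_trace()] with `dx`, `dy` set.
#' @return the trace with `dr` filled in (pixels).
#' @export
derive_dr <- function(trace) {
  stopifnot(inherits(trace, "displacement_trace"))
  n <- length(trace$dx)
  if (n < 2) stop("need at least 2 displacement samples to derive dr")
  xy <- cbind(trace$dx, trace$dy)
  if (all(apply(xy, 2, stats::var) < .Machine$double.eps)) {
    warning("zero-variance displacement scatter; dr set to zeros")
    trace$dr <- numeric(n)
    return(trace)
  }
  v <- stats::prcomp(xy, center = TRUE, scale. = FALSE)$rotation[, 1]
  dr <- as.numeric(xy %*% v)
  cx <- sum((dr - mean(dr)) * (trace$dx - mean(trace$dx)))
  if (cx < 0 || (cx == 0 && sum((dr - mean(dr)) *
                                (trace$dy - mean(trace$dy))) < 0))
    dr <- -dr
  trace$dr <- as.numeric(dr)
  trace
}

#' Convert surface tilt to speckle shift in pixels
#'
#' Near-focused imaging magnifies surface tilt into speckle translation:
#' `d = K * tan(alpha) / pixel_pitch` pixels, with `K` the tilt-to-shift
#' magnification of the [geometry()]. Shared by the simulator (forward model)
#' and any calibration utility (inverse use).
#'
#' @param alpha tilt angle(s) in radians, `|alpha| < pi/2`.
#' @param geom an [geometry()].
#' @return shift in pixels, same length as `alpha`.
#' @export
tilt_to_shift <- function(alpha, geom = geometry()) {
  stopifnot(inherits(geom, "sv_geometry"))
  if (any(abs(alpha) >= pi / 2)) stop("|alpha| must be < pi/2")
  geom$K * tan(alpha) / geom$pixel_pitch
}
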