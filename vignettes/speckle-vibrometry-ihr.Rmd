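---
title: "Methods: speckle vibrometry for instantaneous heart rate"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: speckle vibrometry for instantaneous heart rate}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The measurement model

Laser light scattered by a surface that is rough on the scale of the
wavelength forms a granular interference pattern — speckle — in a defocused
camera. With a *near-focused* arrangement (the camera's focal plane lies
between the surface and the lens, at distance `L1` from the surface and `L2`
from the lens, lens focal length `F`), in-plane and axial motion of the
surface leave the speckle distribution essentially unchanged, while a tilt
`α` of the surface translates the whole pattern by

    d = K · tan α        (metres on the sensor)

`svihr` computes the magnification as `K = L1·L2/F` by default (6.4 m with
the default distances 0.8 m, 0.4 m, 0.05 m). The grouping of the three
distances is deliberately exposed as a single configuration key `K`
(`geometry(K = ...)`): every stage of the pipeline — forward simulation and
displacement analysis alike — depends on the three lengths only through this
one product, so any alternative optical convention is a one-line change and
cannot introduce an internal inconsistency. Dividing by the sensor pixel
pitch (default 5.86 µm, a typical value for the 2.35-MP CMOS sensor class
this geometry targets) converts `d` to pixels. Cardiac chest-wall motion
produces tilts on the order of microradians, hence speckle motion of roughly
a pixel — which is why sub-pixel registration is the core primitive.

### Registration

`register_pair()` implements single-step upsampled cross-correlation: the
integer peak of the FFT cross-correlation, refined by evaluating the
correlation on a ±0.75 px neighbourhood of that peak with a matrix-multiply
DFT at resolution `1/upsampling` (default 100, i.e. 0.01 px). The estimator
returns the shift that maps the first frame onto the second, with the
convention that positive `dx`/`dy` means the pattern moved toward increasing
column/row index (the convention must be fixed somewhere; tests depend on
it). Degenerate inputs — constant frames, mismatched shapes — are refused
rather than guessed at. Frames rendered with periodic spectral shifts need
no windowing; for real video, whose edges reveal new content, a Hann window
flag is available.

### From two axes to one series

The two per-pair shift components are reduced to a single orientation-
independent series `Dr` by projecting each `(dx, dy)` onto the first
principal axis of the shift scatter. The projection was chosen over the
magnitude `sqrt(dx² + dy²)` after explicit consideration: the magnitude
rectifies the waveform (it cannot go negative), which destroys the polarity
of the cardiac deflection and doubles the apparent beat frequency content;
the principal-axis projection preserves the waveform while being invariant
(up to one global sign, fixed by the correlation-with-`dx` rule) under any
common rotation of the shift vectors. This reduction is the main
interpretation risk of the pipeline and is therefore tested directly for
rotation invariance.

## Beat detection

### SV side

The *principal signal* is the band-passed Hilbert envelope of `Dr`:

1. optional cardiac-vibration pre-filter, 10–40 Hz (on by default — raw `Dr`
   of a realistic recording is dominated by respiratory sway, and the
   per-beat deflection is a ~100 ms wavelet whose energy sits in this band);
2. envelope = magnitude of the analytic signal (FFT construction);
3. band-pass 0.5–3 Hz (30–180 bpm), the heart-rate band.

All filters are 4th-order Butterworth applied forward–backward
(`signal::filtfilt`), so neither stage moves peak times — essential when the
quantity of interest is beat-to-beat timing. Peaks are strict 3-point local
maxima accepted above an adaptive threshold: `thresh_frac` (default 0.25) of
a running signal-peak level that is updated after each accepted peak as
`0.125·amplitude + 0.875·level` and re-evaluated at the start of each 5 s
non-overlapping window. The exact thresholding constants used by the
method's antecedents are not published; the defaults here follow the classic
QRS-detector exponential update, are all configuration keys
(`detector_config()`), and — because every quantity is relative — leave peak
times invariant under positive rescaling of the input (tested as a
property). Accepted peaks closer than `refractory_s` (default 0.33 s, the
period of the 3 Hz band edge) keep the larger amplitude. The level is
initialized from the candidate maxima of the first window, so the detector
needs no absolute calibration.

### ECG side

R peaks are detected with the Engelse–Zeelenberg scheme as modified by
Lourenço: differentiate (`y[n] = x[n] − x[n−4]`), smooth with the 5-tap
binomial filter, open a 160 ms search window at each positive threshold
crossing, and take the R peak as the signal maximum in the window. The
crossing threshold is 0.45 of a running peak level (same 0.125/0.875
update), decays linearly once no beat has been seen for 1.5 s (so a
transient loss of amplitude cannot silence the detector permanently), and a
200 ms refractory period follows each accepted peak. Input at rates other
than 300 Hz is resampled internally. Flat or activity-free records return an
empty beat series with a warning rather than an error, since downstream
stages have well-defined behaviour for empty inputs.

## Beat matching and interval selection

Matching is a literal implementation of the published pairing rules: for
R peak `m_j` the search interval is `[0, m_1 + 0.4(m_2 − m_1)]` for the
first peak, `[m_j − 0.4(m_j − m_{j−1}), m_j + 0.4(m_{j+1} − m_j)]` inside,
and `[m_j − 0.4(m_j − m_{j−1}), m_j]` for the last. Three decisions the
printed rules leave open are fixed here: interval bounds are **inclusive**;
an equidistant tie between two SV candidates goes to the **earlier** peak;
and when the nearest candidate was already claimed by an earlier R peak the
R peak is **discarded with no fallback** to the next-nearest, even though a
fallback would raise recall — fidelity to the stated procedure was preferred
over performance. Because 0.4 < 0.5, consecutive search intervals are
disjoint, which makes the matched lists automatically strictly increasing
and duplicate-free; the test suite still verifies both, plus every
individual match/discard decision, against an independent brute-force
checker on 1,000 random instances.

Inter-beat intervals are the consecutive differences of the matched lists.
An ECG interval spanning at least one *discarded* original R peak would
merge two true beats into one long "false interval"; such pairs are removed
from both modalities so SV is not credited (or blamed) for intervals its own
missed detections created. Instantaneous heart rate is `60/IBI` (bpm), and
agreement is summarized by Bland–Altman statistics with differences oriented
ECG − SV (so SV overestimation appears as negative bias) and limits of
agreement at the conventional `bias ± 1.96·SD`. Group-level comparisons use
Shapiro–Wilk as the normality gate at 0.05, Kruskal–Wallis for
distribution-free comparisons, and Welch's *t* for two groups of unequal
size/variance, all via the stock `stats` implementations.

## The simulator: what it emulates and what it does not

`simulate_sv_recording()` generates, under one seed:

- **Speckle**: a circular complex-Gaussian random field band-limited to
  correlation length `grain_px` (a frequency-domain disk pupil), returned as
  intensity. This is the standard statistical model of fully developed
  speckle; its intensity is exponential (contrast 1), which the tests check
  by sample statistics and a Kolmogorov–Smirnov comparison.
- **Rhythm**: RR intervals `60/HR · (1 + rsa·sin(2π f_resp t)) + ε`,
  `ε ~ N(0, sdnn)`, clipped at 0.3 s — mean rate, Gaussian short-term
  variability, and respiratory sinus arrhythmia, the three features the
  beat-matcher and IBI statistics actually exercise.
- **Tilt**: a respiratory sinusoid (default 0.25 Hz, 5 µrad) plus one
  biphasic derivative-of-Gaussian pulse per beat (120 ms support, default
  peak 1 µrad scaled by `damping`). The real ballistocardiographic complex
  has several sub-peaks; a single dominant biphasic deflection is sufficient
  because the detector only requires one prominent deflection per beat, and
  no published waveform model exists for the speckle-tilt signal.
- **Video**: the base pattern spectrally shifted by `K·tan α / pitch` pixels
  along a fixed axis (default 30°, exercising both components), plus
  additive Gaussian sensor noise (default 2% of mean intensity), clipped at
  zero. Periodic spectral shifting introduces no new image content, which is
  what makes the simulator usable as an exact registration oracle.
- **ECG**: a PQRST-like Gaussian-bump template with a dominant narrow R wave
  at each beat time, plus baseline noise; the exact R sample indices are
  exported as ground truth.

Textile layers are modelled only as the scalar `damping` on the cardiac tilt
(plus whatever `noise_sd` the user adds) — no blur, no fabric mechanics.
Deliberately **not** emulated: gross body movement, waveform morphology
changes across sleeping positions, non-periodic frame content at the edges,
camera shot/quantization noise structure, and physiologic arrhythmias.
Consequently, passing end-to-end tests demonstrates that the algorithmic
chain is correct and accurate under its stated model — sub-pixel motion,
one dominant deflection per beat, stationary subject — not that the method
achieves any particular accuracy on real recordings, whose beat-detection
recall/precision is governed by exactly the artifacts the simulator omits.

## Numerical choices and problem sizes

- Registration refinement evaluates a `ceiling(1.5·upsampling)`-point square
  neighbourhood (±0.75 px) around the coarse peak — wide enough that any
  fractional true shift lies inside it.
- The FFT-based analytic signal and spectral shifting assume periodic
  records; both are applied after mean removal and, for real data, can be
  combined with the Hann window flag.
- `detect_sv_peaks` on constant or empty input returns an empty series;
  `derive_dr` on a zero-variance scatter returns zeros with a warning;
  readers reject files with fewer than 2 frames, non-monotonic or
  non-uniform (>1%) timestamps.
- Timestamp alignment resolves offsets to the nearest sample (the source
  synchronization resolution is not specified more finely than that) and is
  idempotent.
- Beat times are kept as 0-based integer sample indices internally so the
  matcher works in exact arithmetic; conversion to seconds happens at the
  interfaces.
- The configuration file is YAML with sections `geometry`, `filters`,
  `detector`, `simulation`; every constant above is a key.

Problem sizes in the shipped checks (chosen to exercise each property at
meaningful scale): the registration sweep uses a 256×256 frame with a
`[-2, 2]` px grid at 0.25 px steps in the test suite and 0.05 px steps in
`scripts/acceptance.R`; the end-to-end recovery test simulates 60 s of
64×64 video at 300 frames/s (18,000 frames, ~70 beats) at 70 bpm with
30 ms SDNN and 2% sensor noise; matcher fidelity is checked on 1,000 random
peak-set instances; RR-law checks use 300 s of simulated rhythm.

## Known limitations

- The mapping from the two-axis shifts to `Dr` in the method's lineage is
  not fully specified; the principal-axis projection documented above is a
  reasoned choice, not a reproduction.
- The adaptive-threshold constants of the SV detector are package defaults,
  not published values.
- `K = L1·L2/F` is one reading of the near-focused magnification; users with
  a calibrated setup should set `K` directly.
- Recall/precision/agreement values obtained on the simulator characterize
  the algorithms, not the physical measurement system: no claim about
  on-skin or on-textile performance of real hardware follows from them.
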