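# svihr — instantaneous heart rate from laser speckle vibrometry

`svihr` implements a contact-free instantaneous heart rate (IHR) pipeline
based on speckle vibrometry (SV). When a laser illuminates an optically rough
surface — skin, a bedsheet, a comforter — a near-focused camera (focal plane
between the surface and the lens) sees a granular speckle pattern, and a tilt
`α` of the surface translates that pattern by

```
d = K · tan α            (metres on the sensor; K = L1·L2/F by default)
```

so that minute cardiac vibrations of the chest wall become measurable
sub-pixel image motion. The package is aimed at researchers prototyping
camera-based vital-sign monitoring (e.g. for sleep studies) who need the full
chain from video to beat-to-beat agreement statistics, plus a physics-based
simulator so every stage can be validated without recorded human data.

The pipeline:

1. **Registration** — each consecutive frame pair is registered with
   upsampled cross-correlation (coarse FFT peak + localized upsampled DFT,
   default up-sampling factor 100, i.e. 0.01-pixel resolution), giving
   per-pair shifts `(dx, dy)`.
2. **Dr** — the two-axis shifts are projected onto the first principal axis
   of their scatter, an orientation-independent scalar displacement series.
3. **Principal signal & SV beats** — a cardiac-band pre-filter, the Hilbert
   envelope, and a 0.5–3 Hz zero-phase band-pass produce the principal
   signal; strict local maxima above an adaptive threshold (fraction of a
   running peak level, re-evaluated in 5 s non-overlapping windows) are the
   SV cardiac peaks.
4. **ECG R peaks** — Engelse–Zeelenberg differentiator with Lourenço-style
   adaptive thresholding and a 200 ms refractory period.
5. **Beat matching** — each R peak `m_j` searches the interval
   `[m_j − 0.4(m_j − m_{j−1}), m_j + 0.4(m_{j+1} − m_j)]` for its nearest SV
   peak, one-to-one without fallback; recall `= |Mvalid|/N_ECG` and
   precision `= |Nvalid|/N_SV`.
6. **IBI selection & agreement** — inter-beat intervals whose ECG span
   contains a discarded R peak ("false intervals") are excluded from both
   modalities; the paired IHR series (`60/IBI`) are compared by Bland–Altman
   analysis (mean bias ± SD, limits of agreement `bias ± 1.96·SD`), with
   Shapiro–Wilk, Kruskal–Wallis and Welch tests available for group
   comparisons.

The simulator renders a fully developed speckle pattern (exponential
intensity, contrast 1) translating under a cardiac + respiratory tilt
waveform through the same `d = K·tan α` model, with sensor noise, a scalar
textile damping knob, and a paired synthetic ECG whose R-peak times are exact
ground truth.

## Worked example

Simulate a 25 s recording (300 frames/s video of 64×64 px, 300 Hz ECG,
65 bpm with 20 ms RR variability) and run the full pipeline:

```r
library(svihr)

cfg <- sim_config(duration_s = 25, mean_hr_bpm = 65, sdnn_s = 0.02, seed = 77L)
rec <- simulate_sv_recording(cfg)
fit <- sv_ihr(rec$frames, rec$ecg, verbose = FALSE)
fit
#> Speckle-vibrometry IHR pipeline result
#>   26 SV peaks, 26 R peaks, 26 matched pairs, 25 paired IBIs
#>   recall 1.000, precision 1.000
#>   IHR agreement: bias 0.006 bpm, SD 0.185 bpm, LOA [-0.36, 0.37] bpm

round(coef(fit), 4)
#>      bias        sd   loa_low  loa_high    recall precision         n
#>    0.0059    0.1850   -0.3567    0.3685    1.0000    1.0000   25.0000
```

All 26 simulated beats are detected in both modalities (recall and precision
1.0), and the SV-derived instantaneous heart rate agrees with the ECG-derived
one to within ±0.37 bpm (95% limits of agreement) with a bias of 0.006 bpm —
i.e. on clean synthetic data the method is accurate to a small fraction of a
beat per minute. `plot(fit)` draws the Bland–Altman plot;
`residuals(fit)` returns the paired IHR differences (ECG − SV).

A thin command-line front end with subcommands `simulate`, `extract`,
`detect-sv`, `detect-ecg`, `match`, `evaluate` and `run-all` is installed at
`inst/cli/svihr` (invoke with `Rscript`).

## Vignette

`vignettes/speckle-vibrometry-ihr.Rmd` documents the measurement model, the
detector and matcher parameters, what the simulator does and does not
emulate, and the package's numerical design choices.
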