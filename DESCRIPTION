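Package: svihr
Title: Instantaneous Heart Rate from Laser Speckle Vibrometry
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for contact-free instantaneous heart rate (IHR) monitoring
    with speckle vibrometry (SV): sub-pixel phase-correlation registration of
    defocused laser-speckle video, reduction of the two-axis speckle shifts to
    an orientation-independent displacement series, cardiac beat detection on
    the band-passed Hilbert envelope with adaptive thresholding, ECG R-peak
    detection (Engelse-Zeelenberg with the Lourenco modifications), one-to-one
    ECG/SV beat matching with false-interval exclusion, and Bland-Altman
    agreement analysis. Includes a physics-based simulator that renders a
    speckle video translating under a cardiac plus respiratory surface-tilt
    waveform together with a paired ECG whose R-peak times are ground truth,
    so the whole pipeline is testable without recorded data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    graphics,
    utils,
    tiff,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
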