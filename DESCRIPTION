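Package: cardiomotor
Title: Cardiac-Phase-Resolved Analysis of Motor Excitability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: End-to-end analysis of cardiac-cycle effects on motor
    excitability from combined EEG, ECG and EMG recordings with TMS event
    streams. Provides ECG-driven systole/diastole windowing (R-peak
    detection, trapezoid-area T-wave-end delineation, equal-length phase
    windows), motor-evoked potential quantification and validity
    filtering, a TMS-EEG artifact-cleaning pipeline (decay-component ICA,
    cubic interpolation, zero-phase filtering, mastoid re-referencing),
    heartbeat-evoked potential extraction with mock-event artifact
    estimation, Morlet-wavelet event-related desynchronization, and a
    statistical engine featuring spatiotemporal cluster-based permutation
    tests, exact Wilcoxon signed-rank tests, repeated-measures ANOVA with
    generalized eta-squared and Greenhouse-Geisser correction,
    linear-mixed-effects distance models and a-priori power analysis. A
    synthetic-session generator with known injected effects supports
    calibration and parameter-recovery testing without any real data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    lme4,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
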