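Package: eegverify
Title: EEG-Based Person Verification from Spectral Band Features
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulation and evaluation pipeline for EEG biometric
    verification. Generates multi-session synthetic EEG cohorts with
    subject-specific band spectra and session-to-session drift, extracts
    per-segment spectral features (normalized peak frequency,
    peak-to-mean band power, relative band power) via common average
    referencing and Welch power spectral density, trains one shallow
    two-output feedforward network per subject with Levenberg-Marquardt
    optimization, and evaluates verification accuracy, sensitivity,
    specificity and precision under within-session and session-disjoint
    train/test splits, including an external-impostor attack and the
    associated ANOVA / Tukey HSD comparisons.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    signal,
    nortest,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
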