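Package: fpqeeg
Title: Quantitative EEG Coma Prognosis with a Limited Frontoparietal Montage
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end quantitative EEG analysis for coma prognosis from a
    four-channel frontoparietal montage (F3, F4, P3, P4 versus Cz).
    Preprocesses multichannel resting-state recordings (epoching, baseline
    calibration, zero-phase Butterworth filtering, amplitude-based artifact
    rejection), extracts 48 features across temporal (burst suppression
    ratio, RMS, Hjorth parameters, higher-order statistics, Shannon
    entropy), spectral (band powers and ratios, peak and spectral-edge
    frequencies) and connectivity (Pearson correlation, mutual information,
    phase locking value, phase-lag index) domains, and runs the prognostic
    statistics: normality-gated group comparison with Benjamini-Hochberg
    correction, partial-correlation pruning, multiple correspondence
    analysis, stepwise logistic modeling with stratified cross-validation,
    and merged-fold ROC/AUC with DeLong intervals. A synthetic comatose-EEG
    cohort generator with controllable burst suppression, rhythm mixtures
    and phase coupling makes every stage testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    car,
    dplyr,
    generics,
    ggplot2,
    purrr,
    rlang,
    signal,
    stats,
    tibble,
    utils,
    yaml
Suggests:
    pROC,
    jsonlite,
    testthat (>= 3.0.0),
    tidyr,
    withr
Config/testthat/edition: 3
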