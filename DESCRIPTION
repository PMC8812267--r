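Package: neuroload
Title: Hybrid EEG-fNIRS Mental Workload Detection
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: A tested pipeline for four-level mental workload detection from
    hybrid EEG-fNIRS recordings acquired during multi-attribute task battery
    (MATB) sessions. Provides a synthetic session generator with controllable
    difficulty-dependent band-power and hemodynamic modulation, EEG and fNIRS
    preprocessing (mastoid re-referencing, Butterworth band-pass and notch
    filtering, downsampling, ocular-artifact regression, motion correction,
    3-second epoching), a feature battery (Welch band powers in theta, alpha,
    beta1 and beta2, channel-pair power differences, eleven per-trace
    statistical descriptors of oxy- and deoxyhemoglobin, neurovascular-coupling
    correlations), SVM-RFE based channel-importance ranking with cross-subject
    aggregation, grid-searched SVM, decision-tree and random-forest evaluation
    of unimodal and fused feature sets, and the accompanying statistical
    reports (behavioral composites, per-channel ANOVA scalp maps with FDR
    correction, band-power contrasts, chromophore level effects).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    signal,
    e1071,
    randomForest,
    rpart,
    jsonlite,
    yaml,
    S4Vectors,
    SummarizedExperiment
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
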