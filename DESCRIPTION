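Package: edasite
Title: Multi-Site Electrodermal Activity Comparison and Signal Quality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: Tools for comparing electrodermal activity (EDA) recorded
    simultaneously at several body sites (forehead, neck, finger, foot).
    Provides preprocessing (resampling, zero-phase Butterworth low-pass
    filtering, stage segmentation), sparse-deconvolution decomposition of
    skin conductance into tonic and phasic components via a non-negative
    convex program solved with an accelerated projected-gradient method,
    standard per-stage EDA indices including an adaptive-threshold skin
    conductance response (SCR) counter, a Welch-periodogram noise-band
    power fraction for motion-artifact assessment, and the statistical
    machinery (within-subject correlations, normality-gated paired
    comparisons, ROC/AUC) used to separate cognitive stress from baseline.
    Includes a seeded multi-site EDA simulator with ground-truth sudomotor
    events for validation.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    signal,
    splines,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    quadprog,
    pROC,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
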