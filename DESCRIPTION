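Package: shockadvice
Title: Shockable Rhythm Detection for Automated External Defibrillators
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A shock advice algorithm (SAA) pipeline for single-channel ECG:
    synthetic shockable/non-shockable cohort generation with patient
    structure, WFDB and CSV record ingestion, non-overlapping 8-s
    segmentation with annotation-driven exclusion rules, a three-stage
    preprocessing filter chain, a 31-feature bank of temporal, spectral and
    complexity ventricular-fibrillation discriminators, gradient-boosting
    split-improvement feature importance with recursive feature elimination
    under patient-wise cross-validation, principal-component feature
    combination, and k-nearest-neighbour classification reporting accuracy,
    sensitivity, specificity and balanced error rate.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
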