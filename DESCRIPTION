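Package: clocksize
Title: Calibration Sample-Size Analysis for DNA-Methylation Age Estimators
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Monte-Carlo tools for deciding how many known-age individuals are
    needed to calibrate an epigenetic clock. Fits sex-stratified, cross-validated
    elastic-net age models on CpG methylation beta values under repeated
    subsampling across a grid of calibration sample sizes, estimates the plateau
    ("true") test-set correlation, and locates the point of stability at which
    the correlation distribution enters and never leaves a corridor of chosen
    width. A sliding-window age-range-removal analysis quantifies how far a
    clock can be extrapolated beyond the age range it was trained on, using
    Cohen's d corridors around the full-data mean absolute error. Includes a
    synthetic methylation-age data generator so the whole pipeline is testable
    without array downloads.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    e1071,
    glmnet,
    jsonlite,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
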