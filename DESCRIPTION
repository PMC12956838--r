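Package: pupilvalence
Title: Pupillometry-Based Classification of Emotional Valence Under
    Controlled Visual Complexity and Arousal
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An analysis pipeline for classifying emotional valence
    (positive vs. negative) from pupil-diameter time series. Provides
    rule-based pupil-trace cleaning (jump and range artifact marking with
    shape-preserving PCHIP gap interpolation and a 30-frame exclusion
    rule), a 45-feature extraction scheme built around the area under the
    pupil curve, gradient-based stimulus spatial-frequency scoring with
    arousal and spatial-frequency binning, dynamic-time-warping k-means
    clustering of stimulus-averaged pupil curves, and a leakage-safe
    grouped cross-validation harness with fold-internal SMOTE, an
    eleven-classifier roster, six standard metrics plus the P4 composite,
    stratified grid runs, mean-ROC aggregation and feature attribution.
    A synthetic-data module generates pupil traces, stimulus metadata and
    grating images with the statistical structure the analysis assumes,
    so the whole pipeline is testable without access to human data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    Rcpp,
    class,
    dplyr,
    e1071,
    jsonlite,
    pracma,
    png,
    purrr,
    randomForest,
    readr,
    rlang,
    rpart,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    xgboost,
    yaml
LinkingTo:
    Rcpp
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
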