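Package: siftecg
Title: SIFT-Based Image Features and a Compact CNN for ECG Rhythm Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A signal-to-image pipeline for classifying long ECG recordings into
    arrhythmia, congestive heart failure and normal sinus rhythm. Records are
    denoised, min-max normalized and segmented; each segment is rendered as an
    RGB raster; scale-invariant keypoints (difference-of-Gaussians extrema with
    subpixel Taylor localization and 128-dimensional gradient-histogram
    descriptors) are detected and overlaid; classes are balanced with SMOTE; and
    a compact three-block convolutional network is trained and scored with a
    full metric stack (per-class and macro accuracy, precision, recall, F1,
    specificity, multiclass Matthews correlation, Cohen's kappa, RMSE),
    stratified k-fold and hold-out cross-validation, and one-way ANOVA with
    Tukey HSD model comparison. Includes a seeded synthetic ECG generator with
    class-distinct PQRST morphology and RR-interval statistics for desk-scale
    experiments.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    png,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    MASS
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
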