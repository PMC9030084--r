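Package: gaitstride
Title: Stride Segmentation, Gait-Phase Division and Stride-Length
    Estimation from Foot-Mounted IMU Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Threshold-free stride segmentation of foot-mounted inertial
    measurement unit (IMU) recordings by subsequence dynamic time warping
    over per-sample neighborhood features, division of each stride into
    push-off, swing, heel-strike and stance phases via major peak-valley-pair
    analysis of sagittal and vertical acceleration (two- and four-reference
    fusion with leave-one-out outlier rejection), and stride-length
    estimation by fusing per-gait-phase regression models (support vector
    regression with a radial kernel, optionally AdaBoost.R2 boosted).
    Includes segment-level evaluation metrics (precision, recall, F-score,
    temporal intersection-over-union, RMSE, relative distance error) and a
    seeded synthetic gait-signal generator with ground-truth stride
    intervals, phase boundaries and stride lengths for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    e1071,
    jsonlite,
    randomForest,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
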