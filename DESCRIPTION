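Package: lidardbh
Title: Genotype-Aware Nonlinear Mixed-Effects Prediction of Tree Diameter
    from UAV LiDAR Metrics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Predicts individual-tree diameter at breast height (DBH) from
    LiDAR-derived tree height and crown diameter in genetically structured
    plantations. Provides allometric base models (logistic, exponential,
    power, Richards) and planting-density dummy-variable extensions fitted by
    nonlinear least squares; a nonlinear mixed-effects (NLME) engine with
    genotype random effects, unstructured covariance, and power or
    exponential residual variance functions estimated by maximum likelihood
    via an alternating Lindstrom-Bates algorithm; EBLUP calibration of
    genotype effects from small subsamples via an iterative three-step
    predictor; calibration sampling-strategy evaluation and
    leave-one-genotype-out cross-validation; and a synthetic stand generator
    with known ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    minpack.lm,
    jsonlite
Suggests:
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
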