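Package: ampeff
Title: Amplification Efficiency Estimation for qPCR Dilution Series
Version: 0.1.0
Authors@R: person("Dilution", "Curve Lab", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Estimators of the qPCR amplification efficiency E from
    dilution-series fluorescence data: direct nonlinear least-squares fit of
    the exponential growth model, generalized least squares on correlated
    pairwise differences, quantification-cycle (Cq) standard-curve
    calibration, and the pairwise intensity-ratio estimator with
    error-propagation weights and outlier-zone diagnostics.  A seedable
    synthetic-data generator (exponential and logistic growth with additive
    Gaussian noise) and a Monte Carlo engine quantify the gap between the
    apparent and the actual precision of estimators built on correlated
    pairwise data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
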