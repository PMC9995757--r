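Package: nearfallr
Title: Wearable-Sensor Home Monitoring, Activity Recognition and
    Fall-Risk Biomarkers
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for in-home monitoring of movement-disorder patients
    with a five-sensor inertial array (chest, both thighs, both shanks).
    Provides the sensor-log data model and session assembly; a
    switched-gain complementary observer that estimates sagittal segment
    tilt and gyroscope bias; a CNN-LSTM activity classifier with
    logistic-regression, support-vector-machine and decision-tree
    baselines over ten daily-living activities including near-falls;
    one-vs-rest confusion statistics and ROC/AUC machinery; behavioral
    fall-risk biomarkers (near-fall counts and frequency, ambulatory
    bouts and their duration power-law exponent, posture frequencies,
    peak chest acceleration); and correlation screening plus a
    multivariable linear model of prospective fall frequency.  A
    scriptable kinematic simulator generates labeled synthetic
    five-sensor sessions so the whole pipeline is testable without
    patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    ggplot2,
    generics,
    nnet,
    e1071,
    rpart,
    withr,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    yaml,
    optparse,
    rhdf5,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
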