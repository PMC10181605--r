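Package: cprshock
Title: Sliding Shock-Advisory ECG Analysis During Cardiopulmonary Resuscitation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for studying continuous (sliding) shock-advisory decisions
    on the defibrillation-pad ECG during cardiopulmonary resuscitation (CPR).
    Provides a synthetic out-of-hospital cardiac-arrest signal generator
    (four rhythm classes, quasi-periodic chest-compression artefacts, 30:2
    compression-to-ventilation protocol with insufflation pauses and a
    compression-free regular analysis window), the sliding hands-off-time
    (sHOT) metric over a 1 s grid of 26 decision times, a fully convolutional
    neural network classifier for raw ECG windows of 5, 10 or 15 s trained
    with a prevalence-weighted binary cross-entropy, ROC operating-point
    selection by maximising sensitivity plus specificity, and performance
    reporting stratified by decision time and by sHOT with Wilson 90%
    confidence intervals and AED performance-goal flags.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Rcpp,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
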