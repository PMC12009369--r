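Package: ttdcast
Title: Time-to-Death Prediction After Terminal Extubation with
    Continuous-Time Recurrent Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com",
           role = c("aut", "cre"))
Description: Tools for predicting time-to-death (TTD) after terminal
    extubation in potential donation-after-circulatory-death (DCD)
    candidates from irregularly sampled clinical time series. Implements
    an ODE-RNN classifier whose hidden state evolves between observations
    by integrating a learned ordinary differential equation and is
    updated at observations by a GRU cell, together with sequence and
    static baselines, a synthetic DCD-cohort simulator with known ground
    truth, temporal-split evaluation (accuracy, ROC-AUC, PR-AUC, F1,
    PPV/NPV, expected calibration error), permutation variable
    importance, and latent-phenotype ("phenoscape") embedding and
    clustering.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    MASS,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices,
    xgboost,
    yaml,
    zoo
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    Matrix,
    cluster,
    nnet,
    pROC,
    testthat (>= 3.0.0),
    uwot,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
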