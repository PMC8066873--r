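Package: nvcoupling
Title: Neurovascular Coupling Estimation from Resting-State EEG-fNIRS
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Estimates global neurovascular coupling (NC) from synchronous
    resting-state electroencephalography (EEG) and functional near-infrared
    spectroscopy (fNIRS) recordings. EEG band power envelopes (theta, alpha,
    beta) are reduced to global timecourses by temporal principal component
    analysis, convolved with a canonical hemodynamic response function and
    regressed, together with short-separation scalp nuisance channels,
    against oxy- and deoxy-hemoglobin concentration changes obtained from
    dual-wavelength optical intensities through the modified Beer-Lambert
    law. Per-subject standardized beta-weights yield six NC metrics that feed
    univariate group tests and a leave-one-out cross-validated linear
    classifier with ROC analysis, bootstrap loading z-scores and recording
    time / channel-count sweeps. A seeded synthetic-cohort generator with
    known ground-truth couplings supports end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Rcpp,
    signal,
    jsonlite,
    stats,
    graphics,
    utils
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
Config/testthat/edition: 3
LinkingTo:
    Rcpp
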