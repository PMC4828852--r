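Package: dsemodel
Title: Multiparametric Diagnostic Models for Dobutamine Stress
    Echocardiography
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Construction and validation of multiparametric logistic
    models that detect stress-induced myocardial ischemia from
    quantitative dobutamine stress echocardiography (DSE) parameters.
    Implements per-segment univariable logistic screening with optimal
    classification thresholds, a threshold-anchored rescaling
    transformation that maps missing measurements to zero, stepwise
    logistic combination into per-patient and per-vessel (LAD, LCX, RCA)
    classifiers, and diagnostic-accuracy evaluation (sensitivity,
    specificity, predictive values with 95 percent confidence intervals)
    on training and held-out cohorts.  A seeded synthetic cohort
    generator emulates the segment-level structure of speckle-tracking
    DSE data so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    glmnet,
    jsonlite,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
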