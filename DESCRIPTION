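Package: slrforest
Title: Sign-Language Subword Recognition from sEMG and Accelerometer
    Signals with Random Forests of Improved Decision Trees
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Recognition of isolated sign-language subwords from
    multi-channel surface electromyography (sEMG) and tri-axial
    accelerometer (ACC) recordings of both forearms.  Provides
    energy-based segmentation of continuous recordings, time- and
    model-based feature extraction (mean absolute value, variance,
    linear prediction coefficients, ACC orientation means), a
    hierarchical "improved decision tree" classifier (pairwise
    pre-classifier, one-/two-handed support vector machine, fuzzy
    K-means hand-orientation stage and per-class multi-stream
    Gaussian-mixture hidden Markov models), class-stratified bootstrap
    bagging of such trees with majority voting, and an evaluation
    harness (three-fold cross-validation, forest-size sweeps and a
    label-noise robustness experiment).  A synthetic-signal generator
    with the statistical structure the classifiers assume makes every
    stage testable without access to human recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    e1071,
    jsonlite,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
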