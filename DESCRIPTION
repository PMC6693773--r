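Package: ventmech2g
Title: Two-Geometry Ventricle Mechanics and Post-PVR Outcome Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-specific right-ventricle biomechanics with separate zero-load
    diastole and systole reference geometries (2G models). Provides an anisotropic
    modified Mooney-Rivlin constitutive law, a total-Lagrangian hexahedral finite
    element inflation solver with follower pressure loads, the iterative pre-shrink
    procedure that estimates zero-load geometries from an imaged minimum-volume
    state, maximum-principal stress/strain extraction at the four cardiac time
    points, and the cohort statistics used to compare Tetralogy of Fallot patients
    with healthy controls and to predict post pulmonary-valve-replacement outcome:
    exact Wilcoxon rank tests, Spearman correlation, and repeated cross-validated
    single-predictor logistic regression trained by gradient descent.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
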