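Package: hemomap
Title: Atlas-Based Mapping of Intracerebral Hemorrhage and Prediction of
    Stroke-Associated Pneumonia from Brain CT
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for relating the spatial distribution of intracerebral
    hemorrhage (ICH) on brain CT to stroke-associated pneumonia (SAP).
    Registers skull-stripped, intensity-normalized CT volumes to a 35-structure
    brain atlas by maximizing binned mutual information (similarity transform
    followed by a B-spline free-form deformation), transfers binary hemorrhage
    masks into atlas space, and derives per-structure bleeding-distribution
    features and volumetric bleeding-extrusion features. Includes stratified
    10-fold cross-validated SAP prediction with logistic regression, support
    vector machine and random forest classifiers, L1-penalized feature-weight
    analysis, per-category hemorrhage probability maps, and a synthetic 3D
    phantom cohort generator with ground-truth transforms for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Rcpp,
    RNifti,
    glmnet,
    e1071,
    randomForest,
    pROC,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
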