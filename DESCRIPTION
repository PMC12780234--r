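Package: pelvamp
Title: Pelvic MRI Morphometry, Shape Radiomics and Reading-Support Model
    Evaluation for Deep Endometriosis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computational toolkit for MRI reading support in deep
    endometriosis: synthetic pelvic phantoms with analytically known ground
    truth, NIfTI volume preprocessing (z-normalization, resampling,
    augmentation, sliding-window inference), segmentation training losses
    (focal, Dice, signed-distance boundary loss) with ensembling, plaque
    depth morphometry with severity grading, ovarian endometriotic cyst
    ellipse-axis and volume-change measurement, 14-feature shape radiomics
    per organ assembled into 56-dimensional vectors, gradient-boosted
    per-location adhesion classification under patient-grouped stratified
    cross-validation, and the evaluation stack (Dice similarity, bounding-box
    IoU detection matching, average precision, reader sensitivity, Cohen's
    kappa).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    stats,
    utils,
    xgboost,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
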