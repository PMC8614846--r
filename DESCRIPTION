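Package: kneejsw
Title: Automated Joint Space Width Measurement and Osteoarthritis
    Severity Prediction from Knee Radiographs
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for automated radiographic assessment of knee
    osteoarthritis. Provides bone segmentation of knee radiographs with a
    residual encoder-decoder network (ResU-Net-18) trained with a
    binary cross-entropy objective, extraction of continuous femoral and
    tibial articular margins from label masks, multi-point and minimum
    joint-space-width (JSW) measurement in a normalized tibial-plateau
    coordinate frame with millimeter calibration, agreement statistics
    against reference measurements (Pearson, Bland-Altman, ICC), and
    gradient-boosted prediction of Kellgren-Lawrence severity and
    48-month progression from JSW features. A phantom generator produces
    synthetic radiograph/mask pairs with analytically known joint gaps,
    synthetic observer pairs and synthetic cohorts so that the whole
    pipeline can be exercised and validated without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    EBImage,
    graphics,
    grDevices,
    jsonlite,
    png,
    pROC,
    Rcpp,
    stats,
    utils,
    xgboost
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
SystemRequirements: zlib
Config/testthat/edition: 3
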