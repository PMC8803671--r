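Package: ssimfem
Title: Statistical Shape and Intensity Models of the Proximal Femur for
    Fracture Risk Classification
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Builds partial least squares (PLS) based statistical shape
    models (SSM), statistical intensity models (SIM) and two-level
    statistical shape-and-intensity models (SSIM) of the proximal femur
    from moment-vector shape descriptors on a shared control-point grid
    and element-wise calibrated bone mineral density fields on
    iso-topological tetrahedral meshes.  Fracture status is classified by
    logistic regression on the leading PLS components under stratified
    balanced 10-fold cross-validation with pooled ROC curves, AUC with
    bootstrap confidence intervals and confusion matrices; an areal
    bone-mineral-density analogue provides the clinical baseline.
    Includes leave-one-out Cook's-distance outlier screening, rigid
    alignment (head-centre/neck-axis initialisation followed by iterative
    closest point), Gaussian-kernel template deformation and moment-vector
    fitting, density calibration against a five-sample phantom, and a
    seeded synthetic cohort generator that emulates the statistical
    structure of a post-menopausal QCT study cohort.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    withr,
    yaml
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
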