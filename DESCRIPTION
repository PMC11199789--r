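Package: habitatr
Title: Habitat Radiomics for Predicting Pathologic Complete Response from CT
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Quantifies intratumoral heterogeneity on pre-treatment CT by
    partitioning a tumour into spatial habitats and modelling treatment
    response from habitat-level radiomic features. Provides a synthetic CT
    lesion phantom generator with planted habitat structure, NIfTI image and
    mask handling with isotropic resampling, a full 3D radiomic feature
    engine (first-order, shape, GLCM, GLRLM, GLSZM, NGTDM and GLDM over a
    20-volume filter bank), voxel-wise feature maps with K-means habitat
    clustering and Calinski-Harabasz elbow selection of the habitat count,
    a t-test/Pearson/LASSO feature-selection cascade feeding a logistic
    regression model, and evaluation by ROC/AUC with DeLong intervals,
    decision-curve analysis, calibration curves and the Hosmer-Lemeshow
    test.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    glmnet,
    RNifti,
    stats,
    tools,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    pROC,
    jsonlite
Config/testthat/edition: 3
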