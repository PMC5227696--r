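Package: voxhier
Title: Voxel-Wise Hierarchical Classification of Longitudinal Brain MRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts conversion from mild cognitive impairment (MCI) to
    Alzheimer's disease from serial co-registered structural MRI. A logistic
    regression classifier is trained at every brain voxel on the subject's
    longitudinal intensity trajectory; voxels whose training accuracy
    (confident value) exceeds a threshold are retained and combined through
    a three-level voxel/patch/image ensemble. Includes last-observation-
    carried-forward completion of irregular visit schedules, pre-conversion
    data filtering, nested stratified cross-validation with hyperparameter
    grids, the four standard performance metrics (ACC, SEN, SPE, AUC), and
    a synthetic longitudinal phantom-cohort generator with ground truth so
    the whole pipeline is testable without clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    RNifti,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
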