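Package: splitlbi
Title: Split Linearized Bregman Iteration for Voxel-Level Gray-Matter
    Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Classification and interpretation of voxel-level gray-matter
    volume data with a logistic model under structured sparsity. The core
    estimator couples the logistic loss to a sparse auxiliary parameter
    through a variable-splitting penalty on a 3D lattice difference
    operator and traces a regularization path by linearized Bregman
    iteration, yielding both a dense predictive estimator and a sparse
    interpretable one. Includes stratified repeated cross-validation with
    ROC/AUC and confidence intervals, key-voxel ranking with plateau
    detection, atlas-level weight aggregation, partial correlation with
    nuisance covariates, cross-cohort transfer testing, and a seeded
    synthetic-cohort generator with planted lesion clusters and
    procedural-bias voxels for support-recovery benchmarking.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    data.table,
    jsonlite,
    Matrix,
    methods,
    Rcpp,
    RNifti,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
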