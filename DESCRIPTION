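Package: carotidrf
Title: Random-Forest Discrimination of Asymptomatic Carotid Stenosis from
    Hemodynamic MRI Features
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates cohorts of asymptomatic unilateral high-grade internal
    carotid artery stenosis (ICAS) patients and healthy controls calibrated to
    published group statistics of eight hemodynamic, oxygenation and
    microvascular MRI parameters; extracts volume-of-interest mean features
    inside and outside individual watershed areas (iWSA) from parameter maps;
    and analyses them with a bagged classification-tree ensemble built from
    scratch with surrogate splits for missing values, out-of-bag permutation
    feature importance, recursive and nested cross-validated feature selection,
    ROC comparison by the fast DeLong test, and a misclassification-probability
    versus cognition subanalysis.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    RNifti,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    pROC
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
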