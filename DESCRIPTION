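Package: crclmcart
Title: Cross-Validated Biomarker Screening and CART Prognostic
    Classification for Colorectal Cancer Liver Metastasis Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Construction and evaluation of immunohistochemistry-based
    prognostic classifiers for patients undergoing resection of colorectal
    cancer liver metastases (CRCLM).  Implements Monte-Carlo
    cross-validated biomarker screening with time-dependent ROC cutoff
    optimisation and stepwise multivariate Cox regression, classification
    and regression tree (CART) modelling of three-year survival over
    dichotomised markers, hazard-ratio based grouping of tree classes into
    prognostic risk groups, permutation-corrected significance of the
    selected classifier, nested-model comparison against
    clinicopathological predictors, and concordance analysis between
    matched primary-tumor and metastasis expression scores.  A calibrated
    synthetic-cohort generator provides proportional-hazards cohorts with
    ordinal marker scores, cross-lesion correlation and censoring so the
    full pipeline can be exercised and validated without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    survival,
    rpart,
    stats,
    utils,
    tools,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
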