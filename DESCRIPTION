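Package: fsestab
Title: Stability-Aware Feature Selection Ensembles for Prognostic
    Prediction in Longitudinal Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Heterogeneous feature-selection ensembles that combine the
    rankings of several filter and embedded selectors (ReliefF, mutual
    information maximisation, conditional mutual information, mRMR,
    chi-squared, SVM-RFE and an l2,1-regularised logistic model) into a
    consensus ranking, then choose the subset size -- and optionally the
    classifier -- that maximises a robustness-performance trade-off (RPT)
    between Kuncheva-index selection stability and a composite
    AUC/sensitivity/specificity score.  Includes a time-window labeller
    that turns longitudinal mild-cognitive-impairment follow-up records
    into stable (sMCI) versus converter (cMCI) learning examples,
    leakage-safe per-fold preprocessing (missing-value filtering,
    mean/mode imputation, gated SMOTE), a repeated stratified
    cross-validation engine with Friedman/Wilcoxon selector comparisons,
    and a synthetic-cohort generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    e1071,
    rpart,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
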