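Package: airwayclassifier
Title: Bronchial Airway Gene-Expression Classifier for Lung Cancer
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Derivation and application of a bronchial-airway gene-expression
    classifier for lung cancer in current and former smokers undergoing
    diagnostic bronchoscopy. Implements the locked 23-gene scoring model
    (genomic gender, smoking and pack-year correlates plus six cancer gene
    cluster means), the multi-step derivation pipeline that produces such
    models (empirical-Bayes moderated t selection, correlation clustering with
    parsimonious cluster representatives, differentially penalized logistic
    regression), cross-platform mean-shift adjustment with training-mean
    imputation for validation cohorts, diagnostic performance evaluation
    (ROC/AUC with DeLong inference, sensitivity/specificity/NPV/PPV with
    Wilson intervals, combination with bronchoscopy), and a synthetic-cohort
    generator with planted ground truth for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite,
    glmnet,
    pROC
Suggests:
    testthat (>= 3.0.0),
    limma,
    mclust,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
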