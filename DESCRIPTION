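Package: fsrcov
Title: Covariate Selection with False Selection Rate Control for RNA-seq
    Differential Expression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Selects relevant covariates for RNA-seq differential expression
    analysis while controlling the false selection rate (FSR). Candidate
    covariates are ranked by a relevance measure computed from per-gene
    moderated-test p-values under a voom-style weighted linear model, removed
    one at a time by backward elimination, and the removal threshold is
    calibrated with Monte-Carlo pseudo-variables that are irrelevant by
    construction. Includes the voom precision-weight and empirical-Bayes
    moderated-statistic machinery, Storey q-values with a histogram estimator
    of the true-null proportion, four pseudo-variable generators crossed with
    two FSR estimators, an inverse-voom count simulator, and a simulation
    harness scoring selection and differential-expression performance.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml,
    jsonlite
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    limma,
    pROC,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
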