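Package: pgxpipe
Title: Candidate-Gene Pharmacogenetic Association Pipeline for Composite
    Clinical Phenotypes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A tested pipeline for candidate-gene association analysis of
    composite clinical phenotypes in opioid-treated cancer-pain cohorts:
    composite phenotype classification from symptom instruments (BPI, MMSE,
    EORTC QLQ-C30), Box-Cox covariate transformation, genotype quality
    control (Hardy-Weinberg tests, pairwise linkage disequilibrium, EM
    haplotype inference), lasso screening of non-genetic predictors with
    serum-concentration interactions, cross-validation-error-penalised
    step-down selection of genetic terms with odds-ratio and
    marginally-standardised relative-risk estimation, generalized
    multifactor dimensionality reduction (GMDR) epistasis search on
    covariate-adjusted score residuals, and permutation-null validation of
    the whole selection procedure. Includes a synthetic-cohort generator
    that emulates the covariate, genotype and outcome structure such
    analyses assume, so every stage is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    glmnet,
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    MASS,
    pROC,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
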