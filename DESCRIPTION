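Package: grspipe
Title: Two-Stage Genetic Risk Score Pipelines for Case-Control Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds and evaluates polygenic risk models for case-control
    studies using a two-stage (training/validation) design. Provides variant
    quality control (exact Hardy-Weinberg test, control minor-allele
    frequency, imputation INFO, windowed linkage-disequilibrium pruning),
    per-variant logistic association screening, L1-penalized (LASSO) logistic
    selection of a sparse weight vector, weighted genetic risk score (GRS)
    construction, quantile-based risk stratification with odds ratios and
    trend tests, and model evaluation by C-statistics, paired nonparametric
    AUC comparison and Hosmer-Lemeshow calibration. A case-control cohort
    simulator with Hardy-Weinberg genotypes, linkage-disequilibrium blocks
    and a logistic disease model makes every stage testable without access
    to individual-level GWAS data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    methods,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    vcfR
LinkingTo: Rcpp
Suggests:
    glmnet,
    knitr,
    optparse,
    pROC,
    rmarkdown,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
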