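Package: mrpath
Title: Two-Sample Mendelian Randomization with Multivariable and Mediation Pathways
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tidyverse-native pipeline for two-sample Mendelian randomization
    from GWAS summary statistics: instrument selection (genome-wide significance,
    greedy LD clumping, palindromic-variant removal, exclusion lists), allele
    harmonization, instrument-strength F statistics, inverse-variance-weighted,
    MR-Egger, weighted/simple median and robust adjusted profile score (RAPS)
    estimators, heterogeneity and pleiotropy sensitivity analyses (Cochran's Q,
    I-squared, Egger intercept, MR-PRESSO, leave-one-out), multivariable MR with
    LASSO mediator screening, and two-step mediation via the coefficient-product
    method with delta-method standard errors and mediated proportions. Includes
    a seeded synthetic GWAS summary-statistics generator with configurable
    causal effects, horizontal pleiotropy and mediator chains, so every stage is
    testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    glmnet,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
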