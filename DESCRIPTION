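Package: cichlidDE
Title: Stage-Wise Differential Expression and Equivalence Testing for
    Multi-Region Brain RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for 3' mRNA-seq count data from multiple
    brain regions sampled within individuals of two closely related species.
    Implements TMM library-size normalization, low-count filtering,
    leading-log-fold-change multidimensional scaling, gene-wise negative
    binomial generalized linear models with Cox-Reid adjusted profile
    likelihood dispersion estimation and empirical Bayes quasi-likelihood
    moderation, quasi-likelihood F-tests for within-species brain-part
    contrasts and between-species interaction contrasts, two-stage
    (screening/confirmation) testing with gene-level false discovery rate
    control, fold-change-threshold tests, two-one-sided-test (TOST)
    equivalence testing of fold changes between species via offset shifting,
    and competitive gene-set enrichment with an inter-gene correlation
    correction. Includes a negative binomial simulator of the clustered
    two-species by six-brain-part design with known truth, and scoring
    utilities for false discovery rate, power and effect-size recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    Matrix,
    purrr,
    Rcpp,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    MASS,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
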