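Package: relapseRF
Title: Nested Cross-Validated Random-Forest Prediction of Relapse After
    Allogeneic Stem Cell Transplantation
Version: 0.1.0
Authors@R:
    person("relapseRF", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reusable pipeline for genomic prediction of relapse in
    recipients of allogeneic haematopoietic stem cell transplantation
    (allo-HSCT): genotype quality control by duplicate-sample concordance
    across GQ/DP hard cutoffs, covariate screening with genetic principal
    components, leave-one-out cross-validated variant selection nested with
    random-forest classification, prediction performance statistics
    (one-sided Mann-Whitney, ROC/AUC with bootstrap confidence intervals,
    AUC power, odds-ratio-of-correct-prediction curves), permutation-based
    variant importance ranking, and replication-cohort evaluation of a
    fixed variant panel. Includes a synthetic-cohort generator with known
    causal structure (MAF spectrum, LD blocks, logistic genotype and
    covariate effects, duplicate samples with GQ-dependent error, missing
    genotypes, and imputed dosages with per-call uncertainty) so that every
    stage can be tested against ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    jsonlite,
    data.table
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    VariantAnnotation,
    optparse,
    withr,
    yaml
Config/testthat/edition: 3
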