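Package: gxescan
Title: Gene-by-Environment Stratified Mendelian Randomization Phenome Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for gene-by-environment Mendelian randomization phenome
    scans (GxE MR-pheWAS): rule-based typing of heterogeneous biobank fields
    into analysis-ready outcomes, stratified association scans of a genetic
    instrument against thousands of outcomes, Cochran's Q heterogeneity
    ranking to separate causal effects from horizontal pleiotropy, step-up
    false-discovery-rate and Bonferroni multiple-testing control,
    collider-bias and FDR-inflation simulation studies for stratified
    designs, and instrumental-variable follow-up estimators (unweighted
    allele scores, bootstrap instrument-strength regression, two-stage IV
    probit). Includes a synthetic biobank generator with known ground truth
    so that every stage of the pipeline can be validated without access to
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    ggplot2,
    MASS,
    nnet,
    purrr,
    Rcpp,
    readr,
    rlang,
    stats,
    tibble,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
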