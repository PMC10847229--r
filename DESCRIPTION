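Package: suvrnet
Title: Metabolic Covariance Networks and Exposure-Response Modeling for
    Regional FDG-PET SUVr Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dose- and sex-resolved analysis of chronic drug
    studies in mouse models imaged with 18F-FDG PET. Implements regional
    SUVr processing (bilateral averaging, cerebellum normalization,
    PCA-based consensus region selection), group-level metabolic covariance
    networks with significance thresholding and signed nodal graph metrics
    (degree, positive/negative strength, clustering coefficient) compared by
    two-sample Kolmogorov-Smirnov tests, multi-resolution consensus
    community detection with a permutation null and reference-partition
    imposition, a one-compartment oral-absorption population pharmacokinetic
    model with allometric scaling and dose covariates (simulation,
    noncompartmental analysis, simplified population fitting, per-animal AUC
    exposure prediction), and exposure-by-sex linear models of log2 gene
    expression and of network summaries. Ships a synthetic-cohort generator
    with planted community covariance structure so the full pipeline is
    testable without animal data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    deSolve,
    mclust,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
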