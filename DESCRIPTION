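Package: triomics
Title: Penalized Bayesian Networks and Serial Mediation for
    Maternal-Offspring Multi-Omics
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.com", role = c("aut", "cre"))
Description: Integrates maternal and offspring ("trio-omics") genotype,
    metabolite and phenotype data in a single analytic pipeline:
    per-metabolite genome-wide association pre-filtering with LD trimming,
    blocklist-constrained sparse Gaussian Bayesian-network estimation by
    block-cyclic coordinate descent over a warm-started penalty solution
    path, extraction of candidate mediation pathways as shortest directed
    paths, and serial mediation modeling with bootstrap inference under a
    discovery/replication protocol.  Ships a synthetic mother-offspring
    cohort generator with Mendelian allele transmission and known
    linear-Gaussian ground truth so every stage is testable without
    restricted cohort data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    Rcpp,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vcfR,
    withr
Config/testthat/edition: 3
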