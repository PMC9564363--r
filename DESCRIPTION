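Package: papnet
Title: Abundance-Profile Clustering, PPI Subnetworks, GO Enrichment and
    Maximal Clique Centrality Hub Ranking
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A seeded, end-to-end pipeline for network-based analysis of
    differential proteomics data: normalizes protein spot abundances into
    log2 abundance profiles, clusters them by k-means and assigns clusters
    to experimental conditions by a centroid score threshold, builds
    first-neighbour protein-protein interaction subnetworks from a
    high-confidence STRING-style edge list, performs per-namespace Gene
    Ontology enrichment (hypergeometric test, Bonferroni control) with
    REVIGO-style semantic redundancy reduction, partitions terms into
    shared and subnetwork-specific groups, and ranks hub genes by Maximal
    Clique Centrality. Ships a synthetic-data generator with planted,
    recoverable structure for validation without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    tools,
    utils
Suggests:
    mclust,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
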