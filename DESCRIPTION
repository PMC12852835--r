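Package: camnet
Title: Community Assembly Null Models and Compositional Association
    Networks for Microbiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Phylogenetic null-model partitioning of microbial community
    assembly processes (beta mean nearest taxon distance, beta nearest
    taxon index and Raup-Crick on Bray-Curtis, with a five-way
    deterministic/stochastic process classification), SparCC compositional
    correlation networks with bootstrap significance and graph topology,
    phylogenetic alpha and beta diversity (Faith's PD, generalized
    UniFrac), distance-based PERMANOVA with marginal sums of squares, and
    host-physiology statistics. Includes a synthetic-community generator
    (phylogenies with Brownian niche traits, count tables assembled under
    controlled ecological processes, compositional counts with planted
    basis correlations, and host metadata with a target correlation
    structure) so every stage can be exercised against known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    ape,
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
    tools,
    utils,
    vegan
Suggests:
    picante,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
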