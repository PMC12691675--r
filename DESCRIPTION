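Package: pdscore
Title: Phylogeny-Deviation Scores for Detecting Species-Specialized Genes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects genes that have diverged in one target species far beyond
    what its phylogenetic position predicts. Per-gene protein distance matrices
    and a 16S rRNA distance matrix are standardized and combined into a 2D
    "distance space" of species pairs; a silhouette-coefficient statistic (the
    PD score) measures how cleanly the target species' pair-points separate
    from the phylogeny-wide trend. Includes GenBank ingest with CDS validity
    filtering, ortholog-group assembly from tabular homology hits, pairwise
    maximum-likelihood protein distances under JTT with Gamma rate variation,
    Calinski-Harabasz and Davies-Bouldin variants of the score, per-site
    Nei-Gojobori dN/dS and amino-acid divergence profiling with run detection,
    and a fully synthetic benchmark generator with known truth labels.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    utils
Suggests:
    cluster,
    withr,
    optparse,
    phangorn,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
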