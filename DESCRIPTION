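Package: clusterbfs
Title: Protein Complex Detection in Weighted PPI Networks by
    Density-Bounded Breadth-First Seed Expansion
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Detects protein complexes in confidence-weighted
    protein-protein interaction networks with the ClusterBFS algorithm:
    every vertex seeds a breadth-first expansion that admits the
    best-connected neighbour while the cluster's weighted density stays
    above a threshold, and highly overlapping clusters are removed by an
    overlap-score redundancy filter. Includes the matching evaluation
    suite (overlap score, threshold match tables, precision, recall,
    F-measure, maximum matching ratio via exact maximum-weight bipartite
    matching), readers and writers for weighted edge lists and MCL-style
    cluster files, a planted-complex network simulator for end-to-end
    validation, and a command-line interface with a density-threshold
    sweep mode.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    generics,
    igraph,
    Matrix,
    optparse,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
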