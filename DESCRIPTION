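Package: netalignr
Title: Fast Global Alignment of Protein Interaction Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Global pairwise alignment of protein-protein interaction
    networks. Computes a diffusion-based node-pair similarity matrix that
    blends topological similarity with elemental (e.g. BLAST-derived
    sequence) similarity, then extracts a one-to-one node matching with
    either a matrix-based greedy half-approximation or an adaptive
    epsilon-scaling auction algorithm for maximum-weight bipartite
    matching. Alignments are assessed topologically (conserved edges,
    common connected subgraphs of the alignment graph) and biologically
    (exact hypergeometric term enrichment of alignment-graph components,
    with sensitivity and specificity summaries). Includes a synthetic
    generator of network pairs with planted node correspondence so the
    whole pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    igraph,
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
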