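Package: keyminer
Title: Mining Hidden Key Molecules in Biomolecular Networks with
    Node-Limited Betweenness Centrality
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Prioritizes "hidden key" molecules in a biomolecular
    knowledge network from a user-supplied gene list. Computes a
    node-limited betweenness centrality (nlBC) restricted to shortest
    paths whose both endpoints lie in the input gene set, with
    endpoint-weight contributions, via a Brandes-style accumulation
    implemented in C++. Statistical significance of each node is
    assessed by Monte-Carlo simulated p-values obtained by recomputing
    the centrality under randomly sampled input sets with permuted
    weights. Includes a multi-source interaction-table parser with a
    distinct-source edge filter, extraction of the shortest-path-union
    subgraph connecting the inputs, Cytoscape SIF/node-attribute export,
    and a seeded synthetic-fixture generator (scale-free background with
    planted ligand-receptor-transcription-factor motifs) for end-to-end
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    igraph,
    jsonlite,
    Rcpp,
    stats,
    utils,
    withr
LinkingTo: Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
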