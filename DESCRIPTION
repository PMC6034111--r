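Package: transientnet
Title: Transient Apoptosis Subnetwork Inference from Developmental
    Expression Time Series
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Identifies transiently regulated gene subnetworks from
    replicated developmental gene-expression time courses. Genes are
    scored for transient (peaked) regulation by a second-order
    polynomial fit to their time series, scores are weighted by
    apoptosis gene-set membership, and a maximum-weight connected
    subgraph is extracted from a protein-interaction network by an
    exact solver (small graphs) or a Steiner-tree style heuristic
    (genome scale). The extracted subnetwork is decomposed into
    modules by spin-glass community detection, modules are tested for
    significance by degree-preserving rewiring and enriched by a
    conditional hypergeometric test, and nodes are classified as
    central or peripheral by betweenness and eigenvector centrality.
    Includes time-resolved gene-set analysis (Welch t statistics
    combined by Stouffer's method with Benjamini-Hochberg correction),
    a synthetic-data generator with a planted transient module for
    end-to-end validation, and readers and writers for expression,
    gene-set (GMT) and STRING-style edge-list formats.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
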