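Package: connectopool
Title: Hierarchical Community Pooling for Brain-Network Regression
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Graph-level regression on weighted brain connectivity networks
    with an interpretable hierarchical graph neural network. Node embeddings
    from symmetric-normalized graph convolutions are repeatedly coarsened by a
    density-based community pooling operator that scores nodes by their total
    latent-feature distance, keeps the top scorers as community centers,
    assigns the remaining nodes to their nearest center, and aggregates member
    features into center-anchored community representations. Per-scale graph
    readouts are fused and passed to a multilayer perceptron trained with a
    joint regression and community-coherence loss. The package also provides
    an effecting-node interpretability pipeline: per-group node selection
    frequencies from the final pooling scale, normalized mutual information
    between group profiles, and a label-permutation significance test. A
    synthetic cohort generator with planted community structure and planted
    signal nodes makes the whole pipeline testable without restricted imaging
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    methods,
    stats,
    utils,
    Rcpp
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    jsonlite,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
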