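Package: bilinkgnn
Title: Link Prediction on Bipartite Association Networks with Enclosing-Subgraph Graph Neural Networks
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts missing links in bipartite association networks (for
    example miRNA-disease association matrices) by classifying labeled h-hop
    enclosing subgraphs with a graph neural network. Each candidate pair's
    local neighborhood is extracted, nodes are annotated with double-radius
    node labels, and a graph convolution that aggregates four propagation
    operators (A, A^2, random-walk normalized and symmetrically normalized
    adjacency) feeds a sort-pooling readout with a one-dimensional
    convolutional classification head. Includes balanced negative sampling,
    leakage-safe k-fold cross-validation, threshold and ranking metrics
    (AUROC, AUPR, MCC and friends), a bipartite stochastic-block-model
    generator for fully synthetic benchmarking, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    yaml,
    methods,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
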