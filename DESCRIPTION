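Package: tlse
Title: Robust Geometric Embedding of Protein-Protein Interaction Networks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Learns low-dimensional metric embeddings of protein-protein
    interaction (PPI) networks from connectivity alone, using a
    t-logistic loss from the t-exponential family whose bounded-influence
    gradient makes the fit robust to spurious and missing interactions.
    Includes the classical multidimensional-scaling baseline on
    shortest-path distances (MDS-GEO), random-graph null models
    (Erdos-Renyi, degree-matched stub rewiring, Barabasi-Albert
    scale-free, stickiness-index, geometric), graphlet-degree-distribution
    (GDD) agreement, ROC/AUC edge-recovery evaluation, edge-reliability
    ranking and noise-perturbation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    igraph,
    Matrix,
    Rcpp,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
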