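Package: sctopo
Title: Geometric and Topological Signatures of Cell States in Single-Cell Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Computes geometric and topological signatures of single-cell
    RNA-seq data. Builds k-nearest-neighbor cell networks from PCA
    embeddings and computes Ollivier-Ricci curvature on their edges via
    exact optimal transport; computes local and relative persistent
    homology of cell neighborhoods with Vietoris-Rips filtrations, and
    persistent homology of per-cell gene networks (statistical
    cell-specific networks with edge-weighted filtrations, and
    node-weighted prior networks with vertex-based clique-complex
    filtrations). Persistence diagrams are summarized as total
    persistence, persistence entropy and Betti curves, and used to flag
    transition cells, quantify differentiation-potential trends, and
    augment cell-type classification.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    igraph,
    pracma,
    e1071,
    randomForest,
    jsonlite,
    yaml,
    withr,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
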