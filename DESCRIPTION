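Package: topopca
Title: Topological Principal Component Analysis for Single-Cell Expression Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Dimensionality reduction for single-cell RNA-seq expression
    matrices with a family of regularized PCA objectives: classical PCA,
    sparse PCA, graph-Laplacian-regularized sparse PCA, and their robust
    L2,1-norm variants regularized by persistent (multi-scale) Laplacians
    built from distance-threshold or k-nearest-neighbor filtrations of a
    cell-cell graph. Includes the surrounding toolkit: expression matrix
    I/O and preprocessing, clustering and classification evaluation
    protocols (ARI, NMI, macro precision/recall/F1, residue-similarity
    scores), hyper-parameter grid-search schemes over filtration weights,
    and a seeded synthetic scRNA-seq data generator.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    MASS,
    jsonlite,
    yaml,
    optparse,
    tibble,
    rlang,
    generics,
    ggplot2,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    pracma,
    withr
Config/testthat/edition: 3
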