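Package: heterocell
Title: Heterophily-Aware Cell-Type Annotation and Novel Cell Detection for scRNA-seq
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Author: Package Author [aut, cre]
Maintainer: Package Author <author@example.org>
Description: Annotates single-cell RNA-seq cell types with a heterophily-aware
    graph neural network trained on a KNN cell graph, combining two-hop message
    passing and cross-layer feature aggregation with a zero-inflated negative
    binomial (ZINB) reconstruction loss, and flags previously uncharacterized
    (novel) cell types with an energy-based score propagated over the two-hop
    neighborhood of the graph. Includes readers/writers for common count-matrix
    formats, quality-control filtering, library-size log-normalization,
    variance-stabilized highly variable gene selection, KNN graph construction,
    node/edge homophily metrics, annotation and open-set evaluation metrics,
    a ZINB count simulator with tunable graph homophily and a designated novel
    cell type, and an end-to-end multi-seed pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    Rcpp,
    methods,
    stats,
    utils,
    jsonlite,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    ggplot2,
    Seurat,
    igraph,
    optparse,
    withr
Config/testthat/edition: 3
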