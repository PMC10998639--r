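Package: chromanno
Title: Cell-Type Annotation of scATAC-seq Data by Hybrid-Graph Variational
    Graph Auto-Encoders
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Semi-supervised transfer of cell-type labels from a labeled
    scRNA-seq reference to an unlabeled scATAC-seq target. Builds an RNA cell
    graph, an ATAC cell graph and a hybrid graph bridged by CCA anchor cells,
    embeds the hybrid and ATAC graphs with parallel variational graph
    auto-encoders whose latent dimension doubles as the label space, and
    decodes a merged reference-target graph whose per-cell-type edge density
    and edge weight flag each prediction as confident or ambiguous. Includes
    TF-IDF/LSI and PCA embeddings, gene-activity computation from peak
    counts, a paired multiome simulator for validation, and standard
    annotation metrics (accuracy, NMI, F1, silhouette width).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    cluster,
    withr,
    jsonlite,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    pROC,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
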