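Package: schsc
Title: Hard-Sample Contrastive Clustering for Single-Cell RNA-Seq
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Clustering of single-cell RNA-seq count matrices by hard-sample
    aware contrastive learning. Normalized expression profiles are smoothed
    with a graph Laplacian filter built on a KNN cell graph, embedded by dual
    attribute and structure encoders, and trained with an InfoNCE-style loss
    whose pair weights emphasise hard positives and hard negatives selected
    via high-confidence pseudo-labels. A zero-inflated negative binomial
    (ZINB) decoder regularizes the embedding against the raw counts. Includes
    readers for MTX/CSV/h5ad count data, a ZINB count simulator with planted
    cluster structure, Leiden/Louvain clustering with binary-searched
    resolution, and clustering metrics (ACC, NMI, ARI, compactness,
    separation).
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    igraph,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    mclust,
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
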