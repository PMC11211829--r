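Package: peaktriplet
Title: Peak-TF-Gene Triplet Inference and Motif-Free TF Binding
    Prediction from Single-Cell Multiome Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Infers peak-TF-gene triplet regulatory associations from
    metacell-aggregated single-cell multiome (RNA + ATAC) matrices using
    complementary Spearman correlation and partial-correlation score
    functions with a motif-score/accessibility regularizer, and predicts
    genome-wide transcription factor binding -- including in accessible
    peaks lacking detected motifs -- by pseudo semi-supervised learning
    on dual SVD embeddings of the peak-accessibility and peak-motif
    matrices, with clustering-guided pseudo-label selection and a per-TF
    regularized logistic-regression classifier. Includes a synthetic
    multiome generator with planted ground truth, ChIP-seq style
    evaluation metrics (AUPR, precision at fixed recall, F1 with a
    shuffle null), and downstream association-discovery analyses.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    data.table,
    igraph,
    glmnet,
    GenomicRanges,
    IRanges,
    stats,
    utils,
    tools,
    methods
Suggests:
    testthat (>= 3.0.0),
    withr,
    rtracklayer,
    jsonlite,
    optparse
Config/testthat/edition: 3
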