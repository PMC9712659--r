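Package: scdownstream
Title: Downstream Statistics for Single-Cell RNA-Seq Count Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Reusable downstream analytics for droplet single-cell RNA-seq
    count matrices: quality-control filters (gene detection, cell count and
    feature percentiles, doublet-score removal, mitochondrial gene removal),
    log-normalization and per-gene scaling, variable-gene selection,
    Wilcoxon rank-sum differential expression with expression-fraction and
    fold-change gating and Benjamini-Hochberg correction, percentile gating
    of marker-positive cells, hypergeometric gene-set enrichment, a
    cluster gene-specificity index with cross-dataset Spearman
    correspondence, rank-based AUC regulon activity and module scores with
    a three-criterion differential-regulon ledger, ligand-receptor pair
    statistics with cluster-label permutation significance, and binned
    pseudotime profiles compared by a cosine-similarity permutation test.
    Includes a negative-binomial synthetic-data generator with planted
    ground truth so every stage is testable end to end without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    Matrix,
    methods,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
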