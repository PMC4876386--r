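Package: mtxpipe
Title: Metatranscriptomic RNA-Seq Processing, Profiling and Mock-Community
    Validation
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for paired-end metatranscriptomic RNA-Seq analysis: quality
    trimming and pair-aware filtering with identical-read collapsing, k-mer
    based sorting of rRNA/tRNA reads from putative mRNA, paired-end overlap
    merging, six-frame gene-fragment prediction, greedy identity clustering
    with cluster-size bookkeeping, best-hit mapping against an annotated gene
    catalog, 16S taxonomic profiling (reservoir subsampling, lineage
    assignment, rank tables, rarefaction), differential-expression statistics
    (median-of-ratios normalization, paired and two-group log-ratio tests,
    Friedman and permutation Spearman tests, PCA), and a mock-community
    simulator with an empirical quality model and ROC/AUC validation harness.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    Biostrings,
    vegan,
    yaml,
    withr,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    DESeq2,
    pROC,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
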