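Package: somgrn
Title: Linked Self-Organizing Maps for Regulatory Network Inference from
    Multi-Omic Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "author@example.org", role = c("aut", "cre"))
Description: Infers transcription-factor target networks by integrating
    chromatin signal (ChIP-seq, ATAC-seq) and RNA expression matrices
    through linked self-organizing maps.  Provides genome partitioning
    from peak calls with RPKM quantification, best-of-trials SOM training
    on a hexagonal lattice, lattice-constrained k-means metaclustering
    with AIC/BIC model selection, nearest-TSS linking of DNA and RNA
    metaclusters, PWM motif scanning with exact dynamic-programming
    p-values and motif-density enrichment, a multi-stage target-filtering
    cascade with FPR/FDR estimation against an unchanging-gene negative
    set, cis-regulatory-module effect scoring, and a synthetic multi-omic
    data generator with a planted ground-truth network for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    igraph,
    jsonlite,
    limma,
    methods,
    Rcpp,
    rtracklayer,
    stats,
    utils
LinkingTo:
    Rcpp
Suggests:
    DESeq2,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
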