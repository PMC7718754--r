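Package: repeatscape
Title: Reference-Free Analysis of Transposable-Element Evolution from
    Genome-Skimming Reads
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for studying transposable-element (TE) evolution from
    low-coverage shotgun reads without a reference assembly: graph-based
    clustering of reads into repeat families, per-family genome-occupancy
    estimation in Mb, molecular-clock dating of LTR-retrotransposon
    activity from read-to-consensus identity distributions, comparative
    multi-species cluster sharing, detection of TE insertions in 1-5 kb
    upstream windows of genes (interval-based and read-pair-based), and
    hypergeometric enrichment of TE-adjacent gene sets.  Includes a
    synthetic-genome simulator that plants repeat families at known
    abundances, insertion ages, sharing patterns, and gene-adjacent
    positions so every stage can be validated against ground truth.
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
    methods,
    Rcpp,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
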