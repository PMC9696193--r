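Package: riboTE
Title: Translational Efficiency Analysis for Matched Ribo-Seq and RNA-Seq
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for quantifying translational regulation
    from matched ribosome-profiling (Ribo-seq) and RNA-seq count matrices.
    Computes per-gene FPKM, translational efficiency (TE) and its fold change
    between conditions, classifies genes as TE-up, TE-down or TE-insensitive,
    partitions the transcriptome/translatome into a nine-quadrant diagram,
    characterises 5'UTR/CDS/3'UTR sequence features (GC content, length,
    Nussinov folding energy, upstream open reading frames) with
    Mann-Whitney comparisons between TE classes, and performs hypergeometric
    gene-set over-representation analysis. A negative-binomial simulator with
    planted TE effects and 5'UTR feature shifts provides ground truth for
    validating every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    Biostrings,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
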