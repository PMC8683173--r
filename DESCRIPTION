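Package: cncnet
Title: Coding-Noncoding Coexpression Network Analysis for lncRNA Target
    Prediction
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: A reproducible pipeline linking differentially expressed long
    noncoding RNAs to candidate target mRNAs in two-group transcriptome
    studies. Implements empirical-Bayes moderated t-test screening with a
    fold-change filter, coding-noncoding (CNC) coexpression network
    construction from Pearson correlations, degree-based hub selection,
    cis-target prediction within a genomic window, hypergeometric gene-set
    over-representation analysis, and 2^-ddCt relative quantification of
    qPCR validation data. Ships a synthetic-data generator that emulates a
    two-group microarray design with planted effects and a machine-readable
    truth table for recovery benchmarking.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    igraph,
    GenomicRanges,
    IRanges,
    ggplot2,
    jsonlite
Suggests:
    limma,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
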