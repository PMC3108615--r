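Package: ridgescan
Title: Chromosomal Domains of Increased and Decreased Gene Expression from
    Transcriptome Maps
Version: 1.0.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Detects chromosomal regions of increased and decreased gene
    expression (RIDGEs and anti-RIDGEs) from gene-ordered expression maps.
    Builds per-tissue and tissue-averaged running-median transcriptome maps,
    calibrates fold thresholds to a genome-coverage target, quantifies chance
    expectation by position permutation, classifies housekeeping and
    tissue-specific genes against a negative-control quantile threshold, tests
    gene sets for over-representation on regions by resampling, tests the
    region distribution of gene lists with Fisher's exact test, and compares
    genomic features between gene groups with the Wilcoxon rank-sum test. A
    synthetic genome and expression simulator with planted expression domains
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    tools,
    jsonlite,
    yaml,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors,
    GenomeInfoDb
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
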