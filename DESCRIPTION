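Package: medipdmr
Title: Comparative MeDIP-Seq Methylome Analysis for Two-Tissue Designs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for comparative MeDIP-seq methylome analysis
    between two tissues (embryo versus endosperm of maize seed as the
    motivating design): CpG-island and shore detection from genome sequence,
    construction of unified methylation regions from per-tissue peak sets,
    count-based differential methylation calling with an exact conditional
    binomial test, overlap annotation against gene features, CpG-content
    promoter/TTR classes and transposable elements, windowed and metagene
    methylation profiles, cross-classification of imprinting-gene methylation
    against expression ratios, and hypergeometric GO-term overrepresentation.
    Includes a seeded synthetic-methylome generator with planted ground truth
    so every stage is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    GenomicRanges,
    IRanges,
    S4Vectors,
    rtracklayer,
    stats,
    tools,
    utils,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    igraph
Config/testthat/edition: 3
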