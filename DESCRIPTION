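Package: tbptools
Title: Tubulin-Based Polymorphism (TBP) Genotyping from Capillary
    Electrophoresis Fragment Data
Version: 0.9.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: End-to-end analysis of Tubulin-Based Polymorphism (TBP)
    intron-length fingerprints resolved by capillary electrophoresis.
    Reads fragment-analysis peak tables, validates runs against a size
    standard, applies RFU height thresholds, consolidates replicate runs
    into consensus profiles, bins amplicon sizes into a binary marker
    matrix, and derives Whittaker pairwise dissimilarities, Shannon
    diversity, barcoding-gap statistics, covariance PCA, neighbor-joining
    trees with bootstrap support and matrix correlations. Includes an
    in-silico TBP amplicon predictor driven by degenerate exon-anchored
    primers and a synthetic-data generator emulating replicated CE runs,
    so the whole pipeline is testable without instrument data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    tools,
    S4Vectors,
    SummarizedExperiment,
    Biostrings,
    IRanges,
    ape,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
biocViews: Genetics, SNP, SequenceMatching, Software
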