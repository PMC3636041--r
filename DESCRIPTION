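Package: devmod
Title: Stage-Specific Transcription Modules and Transcriptome Age Analysis
    for Developmental Time Courses
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Modular analysis of developmental constraints in vertebrate
    embryogenesis. Normalizes a developmental microarray time course with
    spike-in-anchored piecewise-linear equalization and quantile
    normalization, detects stage-specific co-expression modules with a
    seeded Iterative Signature Algorithm (ISA), and compares evolutionary
    gene properties (sequence constraint dN/dS, gene age, orthology class,
    expression conservation across metastages, regulatory-element
    enrichment) between modules with randomization, chi-square and
    hypergeometric tests. Also implements the transcriptome age index
    (TAI) together with its sensitivity battery (signal transformation,
    top-expressed-gene removal, outlier influence). A synthetic-data
    generator plants known module structure and annotation effects so the
    whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    limma,
    IRanges,
    GenomicRanges,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
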