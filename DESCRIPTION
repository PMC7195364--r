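Package: agestrat
Title: Gene Age Stratification and Stress-Expression Enrichment in Yeasts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Assigns an evolutionary age to every protein-coding gene of a
    focal species from orthogroup tables (OrthoFinder-style), combining the
    timing of de novo origin (for single-copy genes) with the timing of gene
    duplication (for multi-copy genes, traced by shared copy number along an
    ordered species ladder) and an optional whole-genome-duplication class.
    Provides the downstream statistics used to relate gene age to stress
    adaptation: conservation-class partitions (single-core, multi-core,
    non-core), normalized differential-expression enrichment ratios per age
    group with two-sided Fisher exact tests, cross-condition overlap counts,
    TPM normalization, bootstrap confidence intervals of the median, and
    amino-acid identity loss per million years against the closest
    congeneric homolog. Includes a gene birth-duplication-loss simulator
    that provides ground truth for validating the sorting method, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    yaml,
    jsonlite,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
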