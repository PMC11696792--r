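Package: cellmig
Title: Quantitative Analysis of Single and Collective Cell Migration
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Toolkit for the quantitative analysis layer of cell-migration
    studies: direction-autocorrelation and exponential-plateau persistence
    fitting of single-cell trajectories, particle image velocimetry (PIV) of
    wound-healing monolayer movies with spurious-vector filtering and
    temporal averaging, wound segmentation and space-time heat maps of speed
    and order parameter, fluorescence line-scan registration and
    edge-enrichment ratios, AlphaFold2 fragment-screen bookkeeping (fragment
    delimitation, MSA filtering, species-paired co-alignments, confidence
    aggregation and ranking), qPCR isoform fractions, and label-free
    proteomics partner-specificity filtering. Includes seeded synthetic-data
    generators with recorded ground truth so every stage is testable by
    parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tiff,
    jsonlite,
    minpack.lm,
    EBImage,
    Biostrings
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
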