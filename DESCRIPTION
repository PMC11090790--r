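Package: regulonkit
Title: Lineage-Specific Transcription-Factor Regulon Construction and
    Activity Scoring
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for characterising a transcription factor's direct
    transcriptional program from ChIP-seq binding and differential
    expression: promoter-window peak-to-gene assignment with TSS-distance
    and localization summaries, hypergeometric peak-set overlap testing,
    integration of bound-gene sets with differential-expression tables,
    gene-signature binding coverage, single-sample gene-set enrichment
    (ssGSEA), construction of signed lineage-specific regulons by
    intersecting binding across cellular contexts with strong expression
    changes, rank-based regulon activity scoring with analytic and
    permutation normalised enrichment scores in bulk and single-cell
    expression, and cutoff-based classification of multiplexed
    immunofluorescence single-cell phenotype tables with spatial export.
    A seeded synthetic-data module generates peaks, gene models,
    differential-expression tables, expression matrices and spatial cell
    tables with ground truth attached.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
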