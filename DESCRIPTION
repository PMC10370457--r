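Package: retrotx
Title: Retrotransposable-Element Transcription Analysis for Esophageal Adenocarcinoma
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Classifies assembled transcript contigs against gene and repeat
    annotations, selects cancer-overexpressed transcripts by percentile
    criteria, computes repeat-subfamily enrichment, diagnostic z-score
    signatures with ROC evaluation, dual-cohort tertile Cox survival
    screens, gene-level exon/intron splicing-deficiency metrics, and
    HERVH-provirus expression subtypes, together with a synthetic-data
    generator that plants known ground truth for recovery testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    jsonlite,
    yaml,
    survival,
    stats,
    utils,
    tools,
    methods,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
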