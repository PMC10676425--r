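Package: splicebind
Title: RBP Splicing-Map Analysis: Differential Splicing Events, CLIP Peaks,
    and Motif Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Integrative analysis of RNA-binding-protein (RBP) mediated
    alternative splicing. Filters and intersects differential-splicing event
    tables in the rMATS v4 dialect, screens candidate RBPs by expression,
    performs sliding-window k-mer enrichment of intronic flanking sequence
    with a Bonferroni-corrected binomial test, characterizes CLIP peaks
    (stringent filtering, width statistics, genomic-feature distribution),
    builds position-dependent RNA splicing maps around sensitive versus
    insensitive exons with a bootstrap null and Poisson enrichment statistic,
    and calls direct RBP targets by intersecting bound genes with spliced
    genes. Ships a seeded synthetic-data generator that plants ground-truth
    motifs, peaks, and splicing effects so the whole pipeline is testable
    end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
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
    stats,
    utils,
    withr,
    Biostrings,
    rtracklayer,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
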