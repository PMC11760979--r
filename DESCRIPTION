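Package: atacdyn
Title: Chromatin Accessibility Dynamics from ATAC-seq Peak Supersets
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Re-calls a universal peak superset across ATAC-seq libraries,
    quantifies normalized tag density per locus, calls loci open or closed
    against a fixed threshold, classifies loci into temporal dynamics
    classes (closed-to-open, open-to-closed, persistently open and their
    subgroups), compares classes between conditions, and integrates
    transcription-factor co-binding with gene expression through
    TSS-window gene assignment, signal pileup profiles and a
    moving-average co-binding density along expression-ranked genes.
    Includes a fully specified synthetic-data generator with planted
    ground truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    tidyr,
    purrr,
    tibble,
    readr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
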