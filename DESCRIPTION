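Package: mslscreen
Title: Dual-Luciferase RNAi Screen Hit Calling and MSL Chromatin Occupancy Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for a cell-based genome-wide RNAi screen for
    regulators of MSL (Male-Specific Lethal) complex targeting in Drosophila,
    and for the chromatin-occupancy analyses that follow it. Implements
    dual-reporter (Firefly/Renilla) plate normalization, control-based plate
    QC, duplicate-concordant hit calling at a plate-SD threshold with a
    Renilla viability filter, the post-screen candidate triage cascade
    (ribosomal-gene removal, exact k-mer dsRNA off-target prediction,
    ambiguous-amplicon removal, multi-reporter validation, functional
    classification), qPCR-style ChIP enrichment normalization, binned
    log2(IP/input) coverage tracks, PWM scanning for MSL recognition
    elements (MREs), peak-MRE occupancy fractions, and sites-by-bins
    enrichment matrices for heatmaps and average profiles. A synthetic-data
    module simulates screening plates with spiked effects and a toy genome
    with planted MREs, chromatin entry sites, and IP/input read pileups, so
    the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    withr,
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    Biostrings,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse
Config/testthat/edition: 3
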