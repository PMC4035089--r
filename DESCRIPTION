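Package: nucleomorphr
Title: Comparative Analysis of Reduced Nucleomorph Genomes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for comparative structural analysis of pairs of small,
    gene-dense genomes such as chlorarachniophyte nucleomorphs: detection of
    near-identical sub-telomeric repeats and degenerate boundary tandem
    arrays, sliding-window GC profiling, intergenic spacer and protein length
    statistics, cataloguing and cross-species comparison of tiny
    (18-23 nt) spliceosomal introns, synteny block detection from shared
    gene order, ortholog presence/absence and core gene sets, and per-gene
    expression and copy-number estimates from base-level coverage. Includes a
    seeded synthetic genome-pair generator with a full ground-truth record
    for validating every detector.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    stringr,
    readr,
    ggplot2,
    generics,
    yaml,
    stats,
    utils,
    methods,
    Biostrings,
    IRanges,
    GenomicRanges,
    S4Vectors,
    rtracklayer,
    Rsamtools,
    GenomicAlignments
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
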