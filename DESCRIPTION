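Package: epidmr
Title: Epigenome-Wide Differential DNA Methylation Region Analysis for
    MeDIP-Seq Window Counts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Window-based epigenome-wide association analysis of MeDIP-seq
    read counts between diseased and non-diseased sample groups: negative
    binomial exact tests on 1 kb genomic windows with common-dispersion
    estimation and trimmed-mean normalization, seed-and-extend assembly of
    differential DNA methylation regions (DMRs), genomic feature
    characterization (CpG density, length, chromosomal clusters, gene
    association), cross-disease overlap analysis with Venn and extended
    overlaps, principal component analysis of RPKM depths at DMR windows,
    and a histopathology incidence arm (control-derived abnormality
    thresholds, observer consensus, disease tables, Fisher's exact
    comparisons). Includes a seeded synthetic-data generator that plants
    multi-window epimutations in negative-binomially dispersed window
    counts so the full pipeline is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors,
    jsonlite,
    cluster
Suggests:
    testthat (>= 3.0.0),
    edgeR,
    Biostrings
Config/testthat/edition: 3
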