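Package: spacerscreen
Title: Genome-Tiling CRISPR Spacer Screens Against Phages
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for pooled, genome-tiling CRISPR type III-A
    spacer screens against staphylococcal phages. Designs tiling spacer
    libraries and their 90-nt synthesis oligos, recovers spacers from
    direct-repeat-flanked amplicon reads, quantifies per-spacer enrichment
    across infection timepoints and host genotypes, maps naively acquired
    spacers to phage and plasmid replicons at single-nucleotide RPM
    resolution, and calls early/late phage operons from time-course RNA-seq
    coverage. Ships a seeded synthetic-data generator that emulates the
    infection/selection experiment so every stage is testable without
    external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    BiocGenerics,
    Biostrings,
    IRanges,
    S4Vectors,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    methods,
    purrr,
    readr,
    rlang,
    stats,
    stringr,
    tibble,
    tidyr,
    tools,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
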