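Package: beemzt
Title: Single-Embryo RNA-Seq Analysis of the Honeybee Maternal-to-Zygotic Transition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to analyse single-embryo RNA-seq data across the honeybee
    (Apis mellifera) maternal-to-zygotic transition, where haploid male and
    diploid female embryos activate their zygotic genomes differently.
    Implements intronic lncRNA discovery with a coding-potential filter and
    genomic locus classification, poly(A)/poly(T) tail detection with
    internal-priming filtering, polyadenylation-site clustering and
    transcript direction inference, splice-junction extraction with
    alternative-splicing event classification, negative-binomial exact tests
    for differential expression with activation-wave assignment, and
    Pearson-correlation co-expression classification. A seeded synthetic-data
    generator builds toy genomes, sex-by-time expression designs with planted
    activation waves, and simulated spliced, tailed alignments with complete
    truth tables, so every stage can be validated against known ground truth.
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
    readr,
    stringr,
    rlang,
    ggplot2,
    generics,
    stats,
    utils,
    tools,
    methods,
    Biostrings,
    GenomicRanges,
    GenomicAlignments,
    IRanges,
    S4Vectors,
    Rsamtools,
    rtracklayer
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
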