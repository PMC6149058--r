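Package: peakrep
Title: Representation Analysis of ChIP-seq Peaks over Genome Sequence
    Classes and Repeat Categories
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for asking where histone-mark ChIP-seq peaks sit in a
    genome and whether any sequence class or repeat category carries more
    (or fewer) of them than its genomic footprint predicts. Builds a
    disjoint genome partition from class interval sets under a
    configurable priority order, computes per-class occupancy baselines,
    assigns each peak one sequence class and at most one repeat category,
    calls direction-specific differential regions between two conditions
    with depth-normalised counts and a cumulative-Poisson tail test, and
    scores over/under-representation with hypergeometric, chi-square and
    Fisher exact statistics under Benjamini-Hochberg correction. A seeded
    synthetic-data generator emulates toy genomes, repeat catalogs, peak
    sets and count tables with known ground truth so the whole pipeline
    runs and validates at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    generics,
    GenomicRanges,
    ggplot2,
    IRanges,
    jsonlite,
    purrr,
    rlang,
    S4Vectors,
    stats,
    tibble,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
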