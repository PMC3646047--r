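Package: genoplast
Title: Comparative Genomics of Genome Plasticity and Rhodopsin Screening
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Desk-scale comparative genomics of closely related bacterial
    genome pairs, built around the mechanisms that shape highly plastic
    genomes such as those of polar sea-ice Roseobacters: bidirectional
    best-hit orthology with global-identity filtering, pan-genome
    partitioning, multilocus sequence analysis with neighbor-joining trees,
    a transposable-element census with per-megabase densities, composite
    calling of regions of enhanced genome plasticity, anchor-based synteny
    with inversion classification, fragment-based average nucleotide
    identity (ANIb), and a two-stage metagenome rhodopsin screen with
    read-length-adaptive validation, xanthorhodopsin subgroup assignment
    and keto-carotenoid binding-site profiling. Includes seeded synthetic
    data generators (genome pairs with planted orthologs, insertion
    sequences, GC-shifted islands and inversions; metagenomes with planted
    rhodopsin fragments) so every stage is testable without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    Biostrings,
    IRanges,
    ape,
    data.table,
    methods,
    stats,
    utils,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr,
    rmarkdown
VignetteBuilder: knitr
Config/testthat/edition: 3
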