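Package: plastomics
Title: Structural Analysis of Chloroplast Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the structural analysis of plastid (chloroplast)
    genomes: detection of the quadripartite LSC/IRb/SSC/IRa architecture and
    its summary statistics, codon usage and relative synonymous codon usage
    (RSCU) with codon-anticodon recognition, microsatellite and minisatellite
    scanning with inverted-repeat deduplication, classification of mate-pair
    orientations to detect the two co-existing SSC-orientation isoforms,
    profiling of plastid DNA insertions (NUPTs) in a nuclear genome,
    parsimony-based inference of inverted-repeat boundary expansion and
    contraction events on a phylogeny, marker allele-diversity summaries,
    reference-similarity read binning with iterative contig elongation, and
    deterministic synthetic-data generators so every stage is testable
    without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    stringr,
    rlang,
    withr,
    ggplot2,
    stats,
    utils,
    ape,
    Biostrings,
    IRanges,
    generics
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
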