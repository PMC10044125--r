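Package: mitochar
Title: Characterization of Circular Mitochondrial Genomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the desk-scale characterization of animal mitochondrial
    genomes: parsing and validation of feature tables with circular coordinate
    arithmetic (sizes, intergenic spacers, strand census), nucleotide
    composition and AT/GC strand-skew statistics per region class, codon usage
    and relative synonymous codon usage (RSCU) under the invertebrate
    mitochondrial genetic code (translation table 5) including incomplete stop
    codons, gene-order rearrangement detection against the ancestral insect
    arrangement, and control-region scanning for motifs, homopolymer stretches,
    microsatellites and tandem repeats. Includes a seeded generator of
    synthetic mitogenomes with a full ground-truth manifest, modelled on the
    box tree moth (Cydalima perspectalis) mitogenome, so every analysis stage
    can be tested without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    optparse,
    purrr,
    readr,
    rlang,
    stringr,
    tibble,
    tidyr,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
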