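# Published summary tables of the box tree moth (Cydalima perspectalis)
# mitogenome, GenBank KY865331 (15,180 bp), shipped as plain-text TSV.
# These printed tables are the desk-scale inputs against which the
# arithmetic of this package is validated.

#' Published annotation of the box tree moth mitogenome
#'
#' The 38-row annotation summary (13 PCGs, 22 tRNAs, 2 rRNAs and the
#' 288 bp A+T-rich control region) of the *Cydalima perspectalis*
#' mitogenome, GenBank KY865331, parsed from the shipped TSV with gene
#' names normalized (`16S` to `rrnL`, `12S` to `rrnS`, `A + T-rich` to
#' `control_region`) and anticodons in the DNA alphabet.
#'
#' @return An annotation tibble in position order.
#' @examples
#' strand_census(cydalima_annotation())
#' @export
cydalima_annotation <- function() {
  read_feature_table(
    system.file("extdata", "cydalima_perspectalis_features.tsv",
                package = "mitochar", mustWork = TRUE),
    genome_length = 15180L
  )
}

#' Published codon counts of the box tree moth mitogenome
#'
#' Codon counts over the 13 protein-coding genes of the *C. perspectalis*
#' mitogenome (terminal stop codons tallied as their own class), with the
#' published RSCU values alongside for cross-checking.
#'
#' @return A tibble with columns `codon` (DNA alphabet), `aa`, `count`,
#'   `rscu_published`.
#' @examples
#' total_sense_codons(cydalima_codon_counts()) # 3723
#' @export
cydalima_codon_counts <- function() {
  raw <- readr::read_tsv(
    system.file("extdata", "cydalima_perspectalis_codon_counts.tsv",
                package = "mitochar", mustWork = TRUE),
    col_types = "ccid", progress = FALSE
  )
  tibble(
    codon = codon_to_dna(raw$Codon),
    aa = raw$AminoAcid,
    count = raw$Count,
    rscu_published = raw$RSCUPublished
  )
}
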