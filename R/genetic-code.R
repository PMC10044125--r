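# Genetic code tables and synonymous-family bookkeeping.

.aa_three <- c(
  A = "Ala", R = "Arg", N = "Asn", D = "Asp", C = "Cys", Q = "Gln", E = "Glu",
  G = "Gly", H = "His", I = "Ile", L = "Leu", K = "Lys", M = "Met", F = "Phe",
  P = "Pro", S = "Ser", T = "Thr", W = "Trp", Y = "Tyr", V = "Val", `*` = "Stop"
)

#' Genetic code with synonymous-family bookkeeping
#'
#' Returns the codon-to-amino-acid map of an NCBI translation table together
#' with the synonymous-family partition used for RSCU. The default, table 5
#' (invertebrate mitochondrial), reassigns ATA to Met, TGA to Trp and
#' AGA/AGG to Ser relative to the standard code, leaving 62 sense codons and
#' the two stops TAA/TAG. Families group codons by amino acid (so Ser has 8
#' members, Leu 6, Arg the 4 CGN codons) and the stop pair forms its own
#' 2-codon family, mirroring how published mitogenome codon tables report a
#' terminal-codon RSCU. The `aa_class` column carries the reporting classes
#' used for amino-acid totals, with Leu split into UUR/CUN and Ser into
#' UCN/AGN.
#'
#' @param table_id NCBI translation table number (default 5).
#' @return A tibble with columns `codon` (DNA alphabet), `aa` (one-letter,
#'   `*` for stop), `family` and `aa_class`.
#' @examples
#' code <- mito_genetic_code()
#' dplyr::count(code, family)
#' @export
mito_genetic_code <- function(table_id = 5) {
  map <- Biostrings::getGeneticCode(as.character(table_id))
  code <- tibble(codon = names(map), aa = unname(map))
  fam3 <- .aa_three[code$aa]
  code$family <- unname(fam3)
  code$aa_class <- dplyr::case_when(
    code$aa == "L" & substr(code$codon, 1, 1) == "T" ~ "Leu(UUR)",
    code$aa == "L" ~ "Leu(CUN)",
    code$aa == "S" & substr(code$codon, 1, 1) == "A" ~ "Ser(AGN)",
    code$aa == "S" ~ "Ser(UCN)",
    TRUE ~ unname(fam3)
  )
  attr(code, "table_id") <- table_id
  code
}

# display convention: codon tables in the mitogenome literature print RNA
# codons (UUA); the internal alphabet is DNA (TTA)
codon_to_rna <- function(x) chartr("T", "U", x)
codon_to_dna <- function(x) chartr("U", "T", x)
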