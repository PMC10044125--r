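#' Round half away from zero
#'
#' Rounds to a fixed number of decimal places with ties going away from zero
#' (the convention used when reporting percentages and skew statistics here),
#' unlike [round()], which rounds ties to even.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Numeric vector of the same length as `x`.
#' @examples
#' round_half_up(0.125, 2) # 0.13, where round(0.125, 2) gives 0.12
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

# split a DNA string into a character vector of single bases
seq_chars <- function(x) {
  if (nchar(x) == 0L) return(character(0))
  strsplit(x, "", fixed = TRUE)[[1L]]
}

# complement without reversing (vectorised over bases or strings)
dna_complement <- function(x) chartr("ACGTNacgtn", "TGCANtgcan", x)

# reverse complement of a single DNA string
dna_revcomp <- function(x) {
  if (nchar(x) == 0L) return(x)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

check_dna <- function(x, what = "sequence", allow_n = TRUE) {
  alphabet <- if (allow_n) "ACGTN" else "ACGT"
  bad <- stringr::str_detect(x, sprintf("[^%s]", alphabet))
  if (any(bad, na.rm = TRUE)) {
    stop(sprintf("%s contains characters outside {%s}",
                 what, paste(seq_chars(alphabet), collapse = ",")),
         call. = FALSE)
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
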