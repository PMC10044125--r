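#' Create a genome record
#'
#' A light container for a (typically circular) mitochondrial genome sequence.
#'
#' @param sequence DNA string over the alphabet A, C, G, T, N.
#' @param id Sequence identifier.
#' @param circular Is the molecule circular? Circularity permits features that
#'   wrap across the origin (end coordinate smaller than start).
#' @return An object of class `mito_genome` with fields `id`, `sequence`,
#'   `circular` and `length`.
#' @examples
#' g <- mito_genome("ATGCATGC", id = "toy")
#' g$length
#' @export
mito_genome <- function(sequence, id = "genome", circular = TRUE) {
  stopifnot(is.character(sequence), length(sequence) == 1L)
  sequence <- toupper(sequence)
  check_dna(sequence, "genome sequence")
  if (nchar(sequence) == 0L) stop("genome sequence must be non-empty", call. = FALSE)
  structure(
    list(id = as.character(id), sequence = sequence,
         circular = isTRUE(circular), length = nchar(sequence)),
    class = "mito_genome"
  )
}

#' @export
print.mito_genome <- function(x, ...) {
  cat(sprintf("<mito_genome> %s: %d bp, %s\n", x$id, x$length,
              if (x$circular) "circular" else "linear"))
  invisible(x)
}

#' Read a single-record FASTA file as a genome
#'
#' @param file Path to a FASTA file containing exactly one sequence.
#' @param circular Circularity flag to attach to the record.
#' @return A [mito_genome()] object.
#' @export
read_genome_fasta <- function(file, circular = TRUE) {
  set <- Biostrings::readDNAStringSet(file)
  if (length(set) == 0L) stop("no sequences found in ", file, call. = FALSE)
  if (length(set) > 1L) {
    warning("multiple sequences in ", file, "; using the first", call. = FALSE)
  }
  mito_genome(as.character(set[[1L]]), id = names(set)[1L], circular = circular)
}

#' Write a genome record to FASTA
#'
#' Lines are wrapped at 70 columns.
#'
#' @param genome A [mito_genome()] object.
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_genome_fasta <- function(genome, file) {
  stopifnot(inherits(genome, "mito_genome"))
  set <- Biostrings::DNAStringSet(genome$sequence)
  names(set) <- genome$id
  Biostrings::writeXStringSet(set, file, width = 70L)
  invisible(file)
}
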