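# Codon extraction, start/stop classification, codon counts and RSCU.

#' Decompose a coding sequence into codons
#'
#' Reads codons in frame from position 1 of the strand-corrected coding
#' sequence. A remainder of 1 or 2 bases becomes `trailing`, interpreted as
#' an incomplete stop codon when it is `T` or `TA` (completed to TAA by
#' polyadenylation of the transcript). The stop status is:
#'
#' * `complete_TAA` / `complete_TAG` — no remainder, terminal stop codon;
#' * `incomplete_T` / `incomplete_TA` — remainder exactly `T` / `TA`;
#' * `non_canonical` — anything else, including genes whose annotated length
#'   is divisible by three but whose final codon is not a stop (published
#'   annotations do contain such rows; the flag surfaces them instead of
#'   guessing).
#'
#' @param seq Strand-corrected coding DNA string (length >= 3).
#' @param gene Optional gene label carried through to the result.
#' @return An object of class `codon_decomposition`: a list with fields
#'   `gene`, `codons`, `start_codon`, `stop_status`, `trailing`, `length`.
#' @examples
#' d <- decompose_gene("ATGAAATAA")
#' d$stop_status # "complete_TAA"
#' @export
decompose_gene <- function(seq, gene = "") {
  stopifnot(is.character(seq), length(seq) == 1L)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < 3L) stop("coding sequence shorter than one codon", call. = FALSE)
  check_dna(seq, paste0("coding sequence of ", gene))
  ncod <- n %/% 3L
  codons <- substring(seq, seq(1L, by = 3L, length.out = ncod),
                      seq(3L, by = 3L, length.out = ncod))
  trailing <- if (n %% 3L == 0L) "" else substr(seq, 3L * ncod + 1L, n)
  stop_status <- if (trailing == "") {
    last <- codons[ncod]
    if (last %in% c("TAA", "TAG")) paste0("complete_", last) else "non_canonical"
  } else if (trailing == "T") {
    "incomplete_T"
  } else if (trailing == "TA") {
    "incomplete_TA"
  } else {
    "non_canonical"
  }
  structure(
    list(gene = gene, codons = codons, start_codon = codons[1L],
         stop_status = stop_status, trailing = trailing, length = n),
    class = "codon_decomposition"
  )
}

#' @export
print.codon_decomposition <- function(x, ...) {
  cat(sprintf("<codon_decomposition> %s: %d codons + %d trailing, start %s, stop %s\n",
              if (nzchar(x$gene)) x$gene else "(unnamed)",
              length(x$codons), nchar(x$trailing), x$start_codon, x$stop_status))
  invisible(x)
}

#' Classify a start codon
#'
#' Mitochondrial protein-coding genes of insects start with ATN codons, with
#' the well-conserved exception of cox1, which starts with CGA.
#'
#' @param codon Character vector of triplets.
#' @return Character vector over {"ATN", "CGA", "other"}.
#' @examples
#' classify_start(c("ATT", "CGA", "GTG"))
#' @export
classify_start <- function(codon) {
  codon <- toupper(codon)
  if (any(nchar(codon) != 3L)) stop("start codon must be a triplet", call. = FALSE)
  dplyr::case_when(
    codon == "CGA" ~ "CGA",
    stringr::str_detect(codon, "^AT[ACGT]$") ~ "ATN",
    TRUE ~ "other"
  )
}

.all_codons <- function() {
  b <- c("A", "C", "G", "T")
  paste0(rep(b, each = 16L), rep(rep(b, each = 4L), 4L), rep(b, 16L))
}

#' Tally codons over gene decompositions
#'
#' Counts every full codon of every gene. With `include_stops = FALSE`
#' (the default, matching published codon tables that count "codons except
#' for the termination codons"), a terminal TAA/TAG codon is excluded while
#' internal occurrences are still counted.
#'
#' @param decompositions A `codon_decomposition` or a list of them.
#' @param include_stops Keep terminal stop codons in the tally?
#' @return A tibble with 64 rows, columns `codon` and `count`.
#' @export
count_codons <- function(decompositions, include_stops = FALSE) {
  if (inherits(decompositions, "codon_decomposition")) {
    decompositions <- list(decompositions)
  }
  codons <- unlist(purrr::map(decompositions, function(d) {
    cc <- d$codons
    if (!include_stops && length(cc) > 0L && cc[length(cc)] %in% c("TAA", "TAG")) {
      cc <- cc[-length(cc)]
    }
    cc
  }))
  lv <- sort(.all_codons())
  tab <- table(factor(codons, levels = lv))
  tibble(codon = lv, count = as.integer(tab))
}

#' Relative synonymous codon usage
#'
#' RSCU of a codon is its count divided by the mean count over its
#' synonymous family; 1 means unbiased usage within the family. Families
#' come from the genetic code (see [mito_genetic_code()]). A family with a
#' zero total gets RSCU 0 for all members and is listed in the
#' `flagged_families` attribute rather than producing 0/0.
#'
#' @param counts Codon-count tibble (columns `codon`, `count`; DNA or RNA
#'   alphabet).
#' @param code Genetic code tibble from [mito_genetic_code()].
#' @return A tibble of class `mito_rscu` with columns `codon`, `aa`,
#'   `aa_class`, `family`, `count`, `rscu`.
#' @examples
#' counts <- tibble::tibble(
#'   codon = c("TTA", "TTG", "CTT", "CTC", "CTA", "CTG"),
#'   count = c(467, 17, 23, 2, 22, 0)
#' )
#' res <- compute_rscu(counts)
#' res$rscu[res$codon == "TTA"] # 5.2768...
#' @export
compute_rscu <- function(counts, code = mito_genetic_code()) {
  stopifnot(is.data.frame(counts), all(c("codon", "count") %in% names(counts)))
  counts <- dplyr::mutate(as_tibble(counts),
                          codon = codon_to_dna(toupper(.data$codon)))
  if (anyDuplicated(counts$codon)) stop("duplicate codons in counts", call. = FALSE)
  out <- code %>%
    dplyr::left_join(dplyr::select(counts, "codon", "count"), by = "codon") %>%
    dplyr::mutate(count = dplyr::coalesce(.data$count, 0L)) %>%
    dplyr::group_by(.data$family) %>%
    dplyr::mutate(
      fam_total = sum(.data$count),
      rscu = ifelse(.data$fam_total > 0,
                    .data$count / (.data$fam_total / dplyr::n()), 0)
    ) %>%
    dplyr::ungroup() %>%
    dplyr::select("codon", "aa", "aa_class", "family", "count", "rscu")
  flagged <- out %>%
    dplyr::group_by(.data$family) %>%
    dplyr::summarise(total = sum(.data$count), .groups = "drop") %>%
    dplyr::filter(.data$total == 0) %>%
    dplyr::pull("family")
  attr(out, "flagged_families") <- flagged
  class(out) <- c("mito_rscu", class(out))
  out
}

#' Amino-acid totals by reporting class
#'
#' Sums codon counts per amino-acid reporting class, with Leu split into
#' UUR/CUN and Ser into UCN/AGN as mitogenome papers report them. Stop
#' codons are excluded unless requested.
#'
#' @inheritParams compute_rscu
#' @param include_stops Include the stop class?
#' @return A tibble with columns `aa_class` and `count`, sorted by
#'   decreasing count.
#' @export
amino_acid_totals <- function(counts, code = mito_genetic_code(),
                              include_stops = FALSE) {
  rs <- compute_rscu(counts, code)
  out <- rs %>%
    dplyr::filter(include_stops | .data$aa != "*") %>%
    dplyr::group_by(.data$aa_class) %>%
    dplyr::summarise(count = sum(.data$count), .groups = "drop") %>%
    dplyr::arrange(dplyr::desc(.data$count))
  out
}

#' Total sense codons
#'
#' Sum of counts over the sense (non-stop) codons of the code.
#'
#' @inheritParams compute_rscu
#' @return Integer scalar.
#' @export
total_sense_codons <- function(counts, code = mito_genetic_code()) {
  rs <- compute_rscu(counts, code)
  as.integer(sum(rs$count[rs$aa != "*"]))
}

#' Codon usage of the protein-coding genes of an annotated genome
#'
#' Extracts every PCG's strand-corrected sequence, decomposes it into codons
#' and returns counts, RSCU and per-gene start/stop classification in one
#' pass: the codon-usage summary a mitogenome paper tabulates.
#'
#' @param genome A [mito_genome()] object.
#' @param annotation Annotation tibble.
#' @param code Genetic code tibble from [mito_genetic_code()].
#' @param include_stops Keep terminal stop codons in the counts?
#' @return A list with elements `rscu` (a `mito_rscu` tibble), `counts`,
#'   `genes` (tibble gene/start_codon/start_class/stop_status) and
#'   `decompositions`.
#' @export
codon_usage <- function(genome, annotation, code = mito_genetic_code(),
                        include_stops = FALSE) {
  ann <- feature_sequences(genome, annotation)
  pcg <- dplyr::filter(ann, .data$category == "PCG")
  if (nrow(pcg) == 0L) stop("annotation contains no PCG features", call. = FALSE)
  dec <- purrr::map2(pcg$seq, pcg$gene, decompose_gene)
  counts <- count_codons(dec, include_stops = include_stops)
  genes <- tibble(
    gene = pcg$gene,
    start_codon = purrr::map_chr(dec, "start_codon"),
    start_class = classify_start(purrr::map_chr(dec, "start_codon")),
    stop_status = purrr::map_chr(dec, "stop_status")
  )
  list(rscu = compute_rscu(counts, code), counts = counts,
       genes = genes, decompositions = dec)
}

#' Write a codon-usage table
#'
#' Codons are printed in the RNA alphabet with RSCU rounded half-up to two
#' decimals, the convention of published codon tables; counts stay exact.
#'
#' @param x A `mito_rscu` tibble from [compute_rscu()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_codon_usage_tsv <- function(x, file) {
  out <- tibble(
    codon = codon_to_rna(x$codon), aa = x$aa, aa_class = x$aa_class,
    count = x$count, rscu = round_half_up(x$rscu, 2)
  )
  readr::write_tsv(out, file, progress = FALSE)
  invisible(file)
}
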