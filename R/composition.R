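# Nucleotide composition and strand-skew statistics.

#' Count bases in a DNA string
#'
#' Case-insensitive; characters outside {A,C,G,T} are tallied as `other`.
#'
#' @param seq DNA string.
#' @return One-row tibble with columns `A`, `C`, `G`, `T`, `other`, `total`.
#' @examples
#' count_bases("AATT")
#' @export
count_bases <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L)
  if (nchar(seq) == 0L) {
    return(tibble(A = 0L, C = 0L, G = 0L, T = 0L, other = 0L, total = 0L))
  }
  s <- toupper(seq)
  a <- stringr::str_count(s, stringr::fixed("A"))
  c_ <- stringr::str_count(s, stringr::fixed("C"))
  g <- stringr::str_count(s, stringr::fixed("G"))
  t <- stringr::str_count(s, stringr::fixed("T"))
  tot <- nchar(s)
  tibble(A = a, C = c_, G = g, T = t,
         other = tot - (a + c_ + g + t), total = tot)
}

# pull (A, T) or (G, C) out of the flexible inputs accepted by the skew
# functions: a count tibble from count_bases(), or two bare numbers
skew_pair <- function(x, y, cols) {
  if (is.data.frame(x)) {
    stopifnot(all(cols %in% names(x)))
    c(x[[cols[1L]]][1L], x[[cols[2L]]][1L])
  } else {
    stopifnot(is.numeric(x), is.numeric(y))
    c(x, y)
  }
}

skew_value <- function(p, q, label, na_on_undefined) {
  if (p + q <= 0) {
    if (na_on_undefined) return(NA_real_)
    stop(label, " skew is undefined: denominator ", label, " total is zero",
         call. = FALSE)
  }
  (p - q) / (p + q)
}

#' AT skew
#'
#' `(A - T) / (A + T)`: the strand asymmetry between adenine and thymine.
#' Scale-invariant, so raw counts and percentages give the same value.
#'
#' @param x A base-count tibble from [count_bases()], or the A count.
#' @param t The T count when `x` is a bare number.
#' @param na_on_undefined Return `NA` instead of erroring when `A + T == 0`.
#' @return Dimensionless value in \[-1, 1\].
#' @examples
#' at_skew(6058, 6231) # -0.0141
#' @export
at_skew <- function(x, t = NULL, na_on_undefined = FALSE) {
  p <- skew_pair(x, t, c("A", "T"))
  skew_value(p[1L], p[2L], "AT", na_on_undefined)
}

#' GC skew
#'
#' `(G - C) / (G + C)`.
#'
#' @param x A base-count tibble from [count_bases()], or the G count.
#' @param c The C count when `x` is a bare number.
#' @inheritParams at_skew
#' @return Dimensionless value in \[-1, 1\].
#' @examples
#' gc_skew(1162, 1729) # -0.196
#' @export
gc_skew <- function(x, c = NULL, na_on_undefined = FALSE) {
  p <- skew_pair(x, c, c("G", "C"))
  skew_value(p[1L], p[2L], "GC", na_on_undefined)
}

#' AT and GC content
#'
#' Percentage of A+T (respectively G+C) bases over the counted total.
#'
#' @param counts Base-count tibble from [count_bases()].
#' @return Percentage in \[0, 100\].
#' @examples
#' at_content(count_bases("AATG")) # 75
#' @export
at_content <- function(counts) {
  stopifnot(is.data.frame(counts))
  if (counts$total[1L] <= 0) stop("empty sequence: content undefined", call. = FALSE)
  100 * (counts$A[1L] + counts$T[1L]) / counts$total[1L]
}

#' @rdname at_content
#' @export
gc_content <- function(counts) {
  stopifnot(is.data.frame(counts))
  if (counts$total[1L] <= 0) stop("empty sequence: content undefined", call. = FALSE)
  100 * (counts$G[1L] + counts$C[1L]) / counts$total[1L]
}

.region_levels <- c("full_genome", "PCGs", "tRNAs", "rRNAs", "control_region")
.region_category <- c(PCGs = "PCG", tRNAs = "tRNA", rRNAs = "rRNA",
                      control_region = "control")

#' Concatenated sequences per region class
#'
#' Builds, for each region class (protein-coding genes, tRNAs, rRNAs,
#' control region), the concatenation of the strand-corrected member feature
#' sequences in annotation order; `full_genome` is the genome itself.
#' Overlapping bases are included once per feature, i.e. the region size is
#' the plain sum of feature lengths, matching how published composition
#' tables total the tRNA and rRNA rows. Region classes absent from the
#' annotation are omitted with a warning.
#'
#' @param genome A [mito_genome()] object.
#' @param annotation Annotation tibble.
#' @return A tibble with columns `region`, `size`, `seq`.
#' @export
region_sequences <- function(genome, annotation) {
  ann <- feature_sequences(genome, annotation)
  rows <- purrr::map(.region_levels, function(region) {
    if (region == "full_genome") {
      return(tibble(region = region, size = genome$length, seq = genome$sequence))
    }
    members <- dplyr::filter(ann, .data$category == .region_category[[region]])
    if (nrow(members) == 0L) {
      warning("no features of class ", .region_category[[region]],
              "; region ", region, " omitted", call. = FALSE)
      return(NULL)
    }
    tibble(region = region, size = sum(members$size),
           seq = paste(members$seq, collapse = ""))
  })
  dplyr::bind_rows(rows)
}

#' Composition and skew table per region class
#'
#' One row per region class in the conventional order (full genome, PCGs,
#' tRNAs, rRNAs, control region) with base percentages, AT/GC content and
#' AT/GC skews. Values are kept at full precision; rounding is applied only
#' when writing with [write_composition_tsv()]. A region in which a skew
#' denominator is zero gets `NA` for that skew rather than aborting the
#' whole table.
#'
#' @param genome A [mito_genome()] object.
#' @param annotation Annotation tibble.
#' @return A tibble of class `mito_composition` with columns `region`,
#'   `size`, `pct_T`, `pct_C`, `pct_A`, `pct_G`, `at_pct`, `gc_pct`,
#'   `at_skew`, `gc_skew`.
#' @export
composition_table <- function(genome, annotation) {
  regions <- region_sequences(genome, annotation)
  out <- purrr::pmap(regions, function(region, size, seq) {
    b <- count_bases(seq)
    tibble(
      region = region, size = size,
      pct_T = 100 * b$T / b$total, pct_C = 100 * b$C / b$total,
      pct_A = 100 * b$A / b$total, pct_G = 100 * b$G / b$total,
      at_pct = at_content(b), gc_pct = gc_content(b),
      at_skew = at_skew(b, na_on_undefined = TRUE),
      gc_skew = gc_skew(b, na_on_undefined = TRUE)
    )
  })
  out <- dplyr::bind_rows(out)
  class(out) <- c("mito_composition", class(out))
  out
}

#' Write a composition table at the conventional printed precision
#'
#' Percentages are rounded half-up to 1 decimal place and skews to 3, the
#' precision used in published mitogenome composition tables.
#'
#' @param x Composition tibble from [composition_table()].
#' @param file Output path.
#' @return `file`, invisibly.
#' @export
write_composition_tsv <- function(x, file) {
  out <- dplyr::mutate(
    as_tibble(x),
    dplyr::across(dplyr::starts_with("pct_"), ~ round_half_up(.x, 1)),
    dplyr::across(dplyr::ends_with("_pct"), ~ round_half_up(.x, 1)),
    dplyr::across(dplyr::ends_with("_skew"), ~ round_half_up(.x, 3))
  )
  readr::write_tsv(out, file, progress = FALSE)
  invisible(file)
}
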