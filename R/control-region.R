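# Scanners for the structural elements of mitochondrial control regions:
# sequence motifs, homopolymer stretches, microsatellites, tandem repeats.
#
# Every scanner returns a "hit" tibble with columns kind, start, end
# (1-based inclusive, in the scanned sequence), unit and copies. Only the
# given strand is scanned, 5'->3'.

hit_tibble <- function(kind = character(0), start = integer(0),
                       end = integer(0), unit = character(0),
                       copies = integer(0)) {
  tibble(kind = kind, start = as.integer(start), end = as.integer(end),
         unit = unit, copies = as.integer(copies))
}

#' Find occurrences of a motif
#'
#' All (possibly overlapping) exact occurrences of `motif` in `seq`; `N` in
#' the motif is a wildcard matching any base. A motif longer than the
#' sequence simply yields no hits.
#'
#' @param seq DNA string to scan.
#' @param motif Motif over {A,C,G,T,N}, non-empty.
#' @return A hit tibble (`kind = "motif"`, `copies = 1`).
#' @examples
#' find_motif("CCATAGGTT", "ATAGG") # one hit at 3..7
#' @export
find_motif <- function(seq, motif) {
  stopifnot(is.character(motif), length(motif) == 1L, nchar(motif) > 0L)
  seq <- toupper(seq); motif <- toupper(motif)
  check_dna(seq, "sequence"); check_dna(motif, "motif")
  if (nchar(motif) > nchar(seq) || nchar(seq) == 0L) return(hit_tibble())
  m <- Biostrings::matchPattern(Biostrings::DNAString(motif),
                                Biostrings::DNAString(seq),
                                fixed = c(pattern = FALSE, subject = TRUE))
  if (length(m) == 0L) return(hit_tibble())
  hit_tibble("motif", Biostrings::start(m), Biostrings::end(m), motif, 1L)
}

#' Find homopolymer runs
#'
#' Maximal runs of a single base with length at least `min_len` (poly-T and
#' poly-A stretches are conserved elements of insect control regions).
#'
#' @param seq DNA string to scan.
#' @param base Single base.
#' @param min_len Minimum run length (>= 2).
#' @return A hit tibble (`kind = "homopolymer"`; `copies` is the run length).
#' @examples
#' find_homopolymer_runs("AATTTTTTTTTTTA", "T", min_len = 10)
#' @export
find_homopolymer_runs <- function(seq, base, min_len = 2L) {
  stopifnot(nchar(base) == 1L, min_len >= 2L)
  seq <- toupper(seq); base <- toupper(base)
  if (nchar(seq) == 0L) return(hit_tibble())
  x <- seq_chars(seq)
  r <- rle(x == base)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & r$lengths >= min_len
  if (!any(keep)) return(hit_tibble())
  hit_tibble("homopolymer", starts[keep], ends[keep],
             base, r$lengths[keep])
}

#' Find microsatellite arrays of a given unit
#'
#' Maximal perfect tandem arrays of `unit` (1-6 bp) with at least
#' `min_copies` full copies. Arrays are left-maximal on whole units; a
#' trailing partial copy of the unit extends `end` but `copies` reports the
#' floor (full copies only).
#'
#' @param seq DNA string to scan.
#' @param unit Repeat unit, 1-6 bp.
#' @param min_copies Minimum number of full copies (>= 3).
#' @return A hit tibble (`kind = "microsatellite"`).
#' @examples
#' find_microsatellites("ATATAT", "AT", min_copies = 3)
#' @export
find_microsatellites <- function(seq, unit, min_copies = 3L) {
  u <- nchar(unit)
  stopifnot(u >= 1L, u <= 6L, min_copies >= 3L)
  seq <- toupper(seq); unit <- toupper(unit)
  n <- nchar(seq)
  if (n < u * min_copies) return(hit_tibble())
  pos <- seq_len(n - u + 1L)
  is_unit <- substring(seq, pos, pos + u - 1L) == unit
  # number of consecutive unit copies starting in phase at each position
  copies_at <- integer(n - u + 1L)
  for (i in rev(pos)) {
    copies_at[i] <- if (!is_unit[i]) 0L else
      1L + if (i + u <= length(is_unit)) copies_at[i + u] else 0L
  }
  starts <- which(copies_at >= min_copies &
                    !(pos - u >= 1L & c(rep(FALSE, u), utils::head(is_unit, -u))))
  if (length(starts) == 0L) return(hit_tibble())
  k <- copies_at[starts]
  after <- starts + k * u
  partial <- vapply(seq_along(starts), function(j) {
    p <- 0L
    while (p < u && after[j] + p <= n &&
           substr(seq, after[j] + p, after[j] + p) == substr(unit, p + 1L, p + 1L)) {
      p <- p + 1L
    }
    p
  }, integer(1))
  hit_tibble("microsatellite", starts, after + partial - 1L, unit, k)
}

# smallest period p of a character vector (p = length(x) if aperiodic)
smallest_period <- function(x) {
  n <- length(x)
  for (p in seq_len(n - 1L)) {
    if (all(x[seq_len(n - p)] == x[(p + 1L):n])) return(p)
  }
  n
}

#' Find tandem repeats
#'
#' All maximal perfect tandem arrays whose smallest period is at least
#' `min_unit`, with at least `min_copies` full copies. Each array is
#' reported once, at its smallest period, so a dinucleotide microsatellite
#' (smallest period 2) is never re-reported as a longer-unit repeat. A
#' trailing partial copy extends `end`; `copies` is the floor.
#'
#' @param seq DNA string to scan.
#' @param min_unit Minimum (smallest) period, >= 2.
#' @param min_copies Minimum number of full copies, >= 2.
#' @return A hit tibble (`kind = "tandem_repeat"`).
#' @examples
#' find_tandem_repeats("ACGACGACG", min_unit = 3, min_copies = 2)
#' @export
find_tandem_repeats <- function(seq, min_unit = 5L, min_copies = 2L) {
  stopifnot(min_unit >= 2L, min_copies >= 2L)
  seq <- toupper(seq)
  n <- nchar(seq)
  if (n < min_unit * min_copies) return(hit_tibble())
  x <- seq_chars(seq)
  out <- list()
  for (u in min_unit:(n %/% min_copies)) {
    eq <- x[seq_len(n - u)] == x[(u + 1L):n]
    r <- rle(eq)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    for (j in which(r$values)) {
      total <- u + r$lengths[j]
      if (total %/% u < min_copies) next
      i <- starts[j]
      span <- x[i:(i + total - 1L)]
      p <- smallest_period(span)
      # canonical report is at the smallest period; spans whose smallest
      # period is below min_unit are not tandem repeats at this scale
      if (p != u) next
      out[[length(out) + 1L]] <- hit_tibble(
        "tandem_repeat", i, i + total - 1L,
        paste(span[seq_len(u)], collapse = ""), total %/% u
      )
    }
  }
  if (length(out) == 0L) return(hit_tibble())
  dplyr::arrange(dplyr::bind_rows(out), .data$start, .data$end)
}

#' Default control-region scan configuration
#'
#' Thresholds for [control_region_report()]. The tandem-repeat minimum unit
#' of 5 with 2 copies keeps dinucleotide microsatellites (reported
#' separately) out of the tandem-repeat class; the poly-T minimum of 10 and
#' poly-A minimum of 8 sit below the 17 bp and 10 bp stretches observed in
#' the box tree moth so both are detectable with margin; the AT
#' microsatellite threshold of 10 copies targets the long (AT)n arrays of
#' lepidopteran control regions.
#'
#' @param motif Motif to scan for (N allowed).
#' @param motif_tail Optional single base; a motif hit immediately followed
#'   by this base is extended by it (the "(A)-like" tail).
#' @param polyt_min,polya_min Minimum poly-T / poly-A run lengths.
#' @param microsat_unit,microsat_min_copies Microsatellite unit and minimum
#'   copies.
#' @param tandem_min_unit,tandem_min_copies Tandem-repeat thresholds.
#' @return A named list of class `cr_scan_config`.
#' @export
cr_scan_defaults <- function(motif = "ATAGG", motif_tail = "A",
                             polyt_min = 10L, polya_min = 8L,
                             microsat_unit = "AT", microsat_min_copies = 10L,
                             tandem_min_unit = 5L, tandem_min_copies = 2L) {
  structure(
    list(motif = motif, motif_tail = motif_tail,
         polyt_min = as.integer(polyt_min), polya_min = as.integer(polya_min),
         microsat_unit = microsat_unit,
         microsat_min_copies = as.integer(microsat_min_copies),
         tandem_min_unit = as.integer(tandem_min_unit),
         tandem_min_copies = as.integer(tandem_min_copies)),
    class = "cr_scan_config"
  )
}

# run the four scanners on a bare sequence with a given configuration
scan_cr_sequence <- function(seq, config = cr_scan_defaults()) {
  motif_hits <- find_motif(seq, config$motif)
  if (nrow(motif_hits) > 0L && !is.null(config$motif_tail)) {
    tail_at <- motif_hits$end + 1L
    has_tail <- tail_at <= nchar(seq) &
      substring(seq, tail_at, tail_at) == toupper(config$motif_tail)
    motif_hits$end[has_tail] <- motif_hits$end[has_tail] + 1L
    motif_hits$unit[has_tail] <- paste0(motif_hits$unit[has_tail],
                                        toupper(config$motif_tail))
  }
  hits <- dplyr::bind_rows(
    motif_hits,
    find_homopolymer_runs(seq, "T", config$polyt_min),
    find_homopolymer_runs(seq, "A", config$polya_min),
    find_microsatellites(seq, config$microsat_unit, config$microsat_min_copies),
    find_tandem_repeats(seq, config$tandem_min_unit, config$tandem_min_copies)
  )
  dplyr::arrange(hits, .data$start, .data$end)
}

#' Scan the control region of an annotated genome
#'
#' Extracts the control-region feature and runs the four scanners (motif,
#' poly-T and poly-A homopolymers, microsatellite, tandem repeats) with the
#' given configuration. Hit coordinates are local to the control region,
#' 1-based inclusive, on the annotated strand.
#'
#' @param genome A [mito_genome()] object.
#' @param annotation Annotation tibble containing a control feature.
#' @param config A [cr_scan_defaults()] configuration.
#' @return A hit tibble sorted by start, with the control-region span
#'   attached as attributes `cr_start`, `cr_end`.
#' @export
control_region_report <- function(genome, annotation,
                                  config = cr_scan_defaults()) {
  ann <- validate_annotation(annotation, genome$length)
  cr <- dplyr::filter(ann, .data$category == "control")
  if (nrow(cr) == 0L) stop("annotation has no control-region feature", call. = FALSE)
  if (nrow(cr) > 1L) stop("annotation has multiple control-region features", call. = FALSE)
  seq <- extract_feature_sequence(genome, cr$start, cr$end, cr$strand)
  if (nchar(seq) == 0L) stop("control region is empty", call. = FALSE)
  hits <- scan_cr_sequence(seq, config)
  attr(hits, "cr_start") <- cr$start
  attr(hits, "cr_end") <- cr$end
  class(hits) <- c("cr_report", class(hits))
  hits
}

#' Check hits against the sequence they were called on
#'
#' Re-extracts every hit by its coordinates and verifies that it literally
#' matches its unit/copies description: homopolymer spans are pure runs of
#' the base, microsatellite and tandem spans begin with `copies` full copies
#' of the unit (plus at most a partial copy), and motif spans match the
#' motif with N wildcards. Used as a self-consistency gate on scanner
#' output.
#'
#' @param seq The scanned DNA string.
#' @param hits A hit tibble.
#' @return `TRUE` invisibly; inconsistent hits raise an error.
#' @export
verify_hits <- function(seq, hits) {
  seq <- toupper(seq)
  for (i in seq_len(nrow(hits))) {
    h <- hits[i, ]
    span <- substr(seq, h$start, h$end)
    ok <- switch(
      h$kind,
      motif = {
        pat <- gsub("N", ".", h$unit)
        nchar(span) == nchar(h$unit) && grepl(paste0("^", pat, "$"), span)
      },
      homopolymer = span == strrep(h$unit, h$copies),
      microsatellite = ,
      tandem_repeat = {
        full <- strrep(h$unit, h$copies)
        startsWith(span, full) &&
          nchar(span) < nchar(full) + nchar(h$unit) &&
          (nchar(span) == nchar(full) ||
             startsWith(h$unit, substr(span, nchar(full) + 1L, nchar(span))))
      },
      FALSE
    )
    if (!isTRUE(ok)) {
      stop(sprintf("inconsistent %s hit at %d..%d (unit %s x %d)",
                   h$kind, h$start, h$end, h$unit, h$copies), call. = FALSE)
    }
  }
  invisible(TRUE)
}
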