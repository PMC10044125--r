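# Feature-table IO and circular coordinate arithmetic.
#
# An annotation is an ordinary tibble with one row per annotated feature and
# columns gene, category (PCG/tRNA/rRNA/control), strand (F/R), start, end
# (1-based, inclusive; end < start marks a feature wrapping the circular
# origin), anticodon, start_codon, stop_codon. All functions below take and
# return plain tibbles so they compose with dplyr verbs.

# alias map between the labels used in published summary tables/figures and
# the canonical names used internally
.gene_aliases <- c(
  "16S" = "rrnL", "12S" = "rrnS", "lrRNA" = "rrnL", "srRNA" = "rrnS",
  "l-rRNA" = "rrnL", "s-rRNA" = "rrnS",
  "A + T-rich" = "control_region", "A+T-rich" = "control_region",
  "AT-rich" = "control_region", "AT-rich region" = "control_region",
  "control region" = "control_region", "CR" = "control_region",
  "D-loop" = "control_region"
)

#' Normalize mitochondrial gene names
#'
#' Maps the label variants found in published tables (`16S`, `12S`,
#' `A + T-rich`, `D-loop`, ...) onto the canonical names `rrnL`, `rrnS` and
#' `control_region`. tRNA names (`trnM`, `trnL1`, `trnS2`, ...) are kept as
#' printed.
#'
#' @param x Character vector of gene labels.
#' @return Character vector of canonical names.
#' @examples
#' normalize_gene_names(c("16S", "trnM", "A + T-rich"))
#' @export
normalize_gene_names <- function(x) {
  hit <- match(x, names(.gene_aliases))
  out <- ifelse(is.na(hit), x, unname(.gene_aliases[hit]))
  as.character(out)
}

# infer the feature category from a canonical gene name
infer_category <- function(gene) {
  dplyr::case_when(
    stringr::str_detect(gene, "^trn") ~ "tRNA",
    gene %in% c("rrnL", "rrnS") | stringr::str_detect(gene, "^rrn") ~ "rRNA",
    gene == "control_region" ~ "control",
    TRUE ~ "PCG"
  )
}

# parse "start-end" / "12,681–14,050" location strings; returns a list of
# integer vectors, NULL entries for malformed fields
parse_location <- function(x) {
  x <- stringr::str_remove_all(x, "[, ]")
  parts <- stringr::str_split(x, "[–—-]")
  lapply(parts, function(p) {
    if (length(p) != 2L || any(!stringr::str_detect(p, "^[0-9]+$"))) return(NULL)
    as.integer(p)
  })
}

#' Read a mitogenome feature table
#'
#' Parses the tab-separated feature-table dialect used throughout this
#' package: a header line followed by one row per feature. Two coordinate
#' styles are accepted: explicit `Start`/`End` columns, or a single `Location`
#' column holding `start-end` ranges (en-dash or hyphen, optional thousands
#' separators), as published mitogenome summary tables print them. Column
#' names are matched case-insensitively; a `Category` column is optional and
#' inferred from gene names when absent. Anticodons are normalized to the DNA
#' alphabet (U becomes T). When a declared `Size` column is present it is
#' checked against the computed feature length and mismatches raise a warning
#' reporting both values (published tables contain arithmetic slips; they
#' should be surfaced, not silently trusted).
#'
#' @param file Path to a TSV file, or a character vector of lines.
#' @param normalize Normalize gene names via [normalize_gene_names()]?
#' @param genome_length Optional genome length, used to compute the size of
#'   origin-wrapping features during the declared-size check.
#' @return A tibble with columns `gene`, `category`, `strand`, `start`, `end`,
#'   `anticodon`, `start_codon`, `stop_codon`, in file order.
#' @seealso [write_feature_table()]
#' @export
read_feature_table <- function(file, normalize = TRUE, genome_length = NULL) {
  lines <- if (length(file) == 1L && !grepl("\n", file) && file.exists(file)) {
    readr::read_lines(file)
  } else {
    unlist(stringr::str_split(file, "\n"))
  }
  lines <- lines[!stringr::str_detect(lines, "^\\s*$")]
  if (length(lines) < 1L) stop("feature table has no header line", call. = FALSE)

  raw <- suppressWarnings(readr::read_tsv(
    I(paste(lines, collapse = "\n")),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE, show_col_types = FALSE
  ))
  names(raw) <- tolower(gsub("[ _]", "", names(raw)))

  col <- function(...) {
    for (nm in c(...)) if (nm %in% names(raw)) return(raw[[nm]])
    rep(NA_character_, nrow(raw))
  }

  gene <- col("gene", "name", "feature")
  if (all(is.na(gene))) stop("feature table lacks a Gene column", call. = FALSE)

  if ("location" %in% names(raw)) {
    loc <- parse_location(raw$location)
    bad <- which(vapply(loc, is.null, logical(1)))
    if (length(bad) > 0L) {
      stop(sprintf("malformed coordinate in Location field at data row %d: '%s'",
                   bad[1L], raw$location[bad[1L]]), call. = FALSE)
    }
    start <- vapply(loc, `[`, integer(1), 1L)
    end <- vapply(loc, `[`, integer(1), 2L)
  } else {
    num <- function(x, what) {
      x <- stringr::str_remove_all(x, "[, ]")
      bad <- which(!is.na(x) & !stringr::str_detect(x, "^[0-9]+$"))
      if (length(bad) > 0L) {
        stop(sprintf("malformed coordinate in %s field at data row %d: '%s'",
                     what, bad[1L], x[bad[1L]]), call. = FALSE)
      }
      as.integer(x)
    }
    start <- num(col("start"), "Start")
    end <- num(col("end"), "End")
    if (all(is.na(start)) || all(is.na(end))) {
      stop("feature table needs either Start/End columns or a Location column",
           call. = FALSE)
    }
  }

  strand <- toupper(col("strand"))
  strand[is.na(strand) | strand == ""] <- NA_character_
  known <- is.na(strand) | strand %in% c("F", "R")
  if (!all(known)) {
    stop(sprintf("unknown strand symbol '%s' at data row %d (expected F or R)",
                 strand[which(!known)[1L]], which(!known)[1L]), call. = FALSE)
  }

  gene_norm <- if (normalize) normalize_gene_names(gene) else gene
  category <- col("category")
  category[is.na(category)] <- infer_category(normalize_gene_names(gene))[is.na(category)]
  # the control region carries no strand in published tables; scan convention
  # is the majority strand
  strand[is.na(strand) & category == "control"] <- "F"
  if (anyNA(strand)) {
    stop(sprintf("missing strand at data row %d", which(is.na(strand))[1L]),
         call. = FALSE)
  }

  if (anyDuplicated(gene_norm)) {
    dup <- unique(gene_norm[duplicated(gene_norm)])
    stop("duplicate gene name(s) in feature table: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }

  tidy_triplet <- function(x) {
    x <- toupper(chartr("U", "T", x))
    x[x %in% c("", "-", "–", "NA")] <- NA_character_
    x
  }

  ann <- tibble(
    gene = gene_norm,
    category = category,
    strand = strand,
    start = start,
    end = end,
    anticodon = tidy_triplet(col("anticodon")),
    start_codon = tidy_triplet(col("startcodon")),
    stop_codon = tidy_triplet(col("stopcodon"))
  )

  declared <- col("size", "sizebp", "length")
  if (!all(is.na(declared))) {
    declared <- as.integer(stringr::str_remove_all(declared, "[, ]"))
    computed <- feature_length(ann$start, ann$end, genome_length = genome_length,
                               .allow_na_wrap = TRUE)
    off <- which(!is.na(declared) & !is.na(computed) & declared != computed)
    if (length(off) > 0L) {
      warning(sprintf(
        "declared Size disagrees with computed length for: %s",
        paste(sprintf("%s (declared %d, computed %d)",
                      ann$gene[off], declared[off], computed[off]),
              collapse = "; ")), call. = FALSE)
    }
  }
  ann
}

#' Write a feature table
#'
#' Emits the canonical dialect (columns Gene, Category, Strand, Start, End,
#' Anticodon, StartCodon, StopCodon) that [read_feature_table()] parses back
#' to an identical annotation. Coordinates are written as bare integers with
#' no thousands separators.
#'
#' @param annotation Annotation tibble.
#' @param file Output path, or `NULL` to return the lines.
#' @return The output lines, invisibly.
#' @export
write_feature_table <- function(annotation, file = NULL) {
  annotation <- validate_annotation(annotation)
  fmt <- function(x) ifelse(is.na(x), "", as.character(x))
  header <- paste(c("Gene", "Category", "Strand", "Start", "End",
                    "Anticodon", "StartCodon", "StopCodon"), collapse = "\t")
  rows <- if (nrow(annotation) == 0L) character(0) else {
    paste(fmt(annotation$gene), fmt(annotation$category), fmt(annotation$strand),
          fmt(annotation$start), fmt(annotation$end), fmt(annotation$anticodon),
          fmt(annotation$start_codon), fmt(annotation$stop_codon), sep = "\t")
  }
  lines <- c(header, rows)
  if (!is.null(file)) readr::write_lines(lines, file)
  invisible(lines)
}

#' Validate an annotation tibble
#'
#' Checks the structural invariants of an annotation: required columns,
#' unique gene names, positive coordinates, strands in {F, R}, and anticodons
#' confined to tRNA rows (a tRNA without an anticodon draws a warning, an
#' anticodon on a non-tRNA is an error). Missing optional columns are added
#' as NA.
#'
#' @param annotation Annotation tibble (or data.frame).
#' @param genome_length Optional genome length; when given, coordinates are
#'   checked against it.
#' @return The annotation as a tibble with the full column set.
#' @export
validate_annotation <- function(annotation, genome_length = NULL) {
  ann <- as_tibble(annotation)
  need <- c("gene", "strand", "start", "end")
  miss <- setdiff(need, names(ann))
  if (length(miss) > 0L) {
    stop("annotation lacks column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  }
  if (!"category" %in% names(ann)) ann$category <- infer_category(ann$gene)
  for (nm in c("anticodon", "start_codon", "stop_codon")) {
    if (!nm %in% names(ann)) ann[[nm]] <- NA_character_
  }
  if (anyDuplicated(ann$gene)) {
    stop("duplicate gene name(s): ",
         paste(unique(ann$gene[duplicated(ann$gene)]), collapse = ", "),
         call. = FALSE)
  }
  if (nrow(ann) > 0L) {
    stopifnot(is.numeric(ann$start), is.numeric(ann$end))
    if (any(ann$start < 1L | ann$end < 1L)) {
      stop("coordinates must be >= 1", call. = FALSE)
    }
    if (!all(ann$strand %in% c("F", "R"))) {
      stop("strand must be 'F' or 'R'", call. = FALSE)
    }
    if (!is.null(genome_length) &&
        any(ann$start > genome_length | ann$end > genome_length)) {
      stop("coordinates exceed genome length ", genome_length, call. = FALSE)
    }
    stray <- !is.na(ann$anticodon) & ann$category != "tRNA"
    if (any(stray)) {
      stop("anticodon given for non-tRNA feature(s): ",
           paste(ann$gene[stray], collapse = ", "), call. = FALSE)
    }
    if (any(ann$category == "tRNA" & is.na(ann$anticodon))) {
      warning("tRNA feature(s) without anticodon", call. = FALSE)
    }
  }
  ann
}

#' Is an annotation a complete mitogenome annotation?
#'
#' A complete animal mitogenome annotation carries 13 protein-coding genes,
#' 22 tRNAs, 2 rRNAs and one control region.
#'
#' @param annotation Annotation tibble.
#' @return Logical scalar.
#' @export
is_complete_annotation <- function(annotation) {
  tab <- table(factor(annotation$category,
                      levels = c("PCG", "tRNA", "rRNA", "control")))
  all(tab == c(PCG = 13L, tRNA = 22L, rRNA = 2L, control = 1L))
}

#' Feature length on a circular genome
#'
#' Lengths in bp of 1-based inclusive ranges. A range with `end < start`
#' wraps the circular origin and requires `genome_length`.
#'
#' @param start,end Integer vectors of coordinates.
#' @param genome_length Genome length in bp (needed for wrapping features and
#'   for bounds checking).
#' @param .allow_na_wrap Internal: return NA instead of erroring for wrapping
#'   features when `genome_length` is unknown.
#' @return Integer vector of lengths.
#' @examples
#' feature_length(1, 68)            # 68
#' feature_length(12681, 14050)     # 1370
#' feature_length(5, 2, genome_length = 6) # wraps: 4
#' @export
feature_length <- function(start, end, genome_length = NULL,
                           .allow_na_wrap = FALSE) {
  stopifnot(length(start) == length(end))
  if (!is.null(genome_length) &&
      any(start > genome_length | end > genome_length, na.rm = TRUE)) {
    stop("coordinates exceed genome length ", genome_length, call. = FALSE)
  }
  wraps <- !is.na(start) & !is.na(end) & end < start
  if (any(wraps) && is.null(genome_length)) {
    if (!.allow_na_wrap) {
      stop("end < start implies an origin-wrapping feature; supply genome_length",
           call. = FALSE)
    }
  }
  out <- end - start + 1L
  if (any(wraps)) {
    out[wraps] <- if (is.null(genome_length)) NA_integer_ else
      as.integer(genome_length - start[wraps] + 1L + end[wraps])
  }
  as.integer(out)
}

#' Per-feature lengths of an annotation
#'
#' @param annotation Annotation tibble.
#' @param genome_length Genome length in bp.
#' @return The annotation with a `size` column appended.
#' @export
feature_lengths <- function(annotation, genome_length = NULL) {
  ann <- validate_annotation(annotation, genome_length)
  dplyr::mutate(ann, size = feature_length(.data$start, .data$end, genome_length))
}

#' Intergenic spacers around a circular annotation
#'
#' The spacer after feature *i* is `start(i+1) - end(i) - 1`; negative values
#' mark overlapping neighbours. The last feature pairs with the first across
#' the circular origin. Published mitogenome tables print this quantity as
#' "intergenic length" attached to the preceding gene.
#'
#' @param annotation Annotation tibble sorted by start coordinate.
#' @param genome_length Genome length in bp (for the closing spacer).
#' @return A tibble with columns `gene`, `next_gene`, `spacer`.
#' @examples
#' ann <- tibble::tibble(gene = c("a", "b"), strand = "F",
#'                       start = c(1, 4), end = c(3, 6))
#' intergenic_lengths(ann, genome_length = 6)
#' @export
intergenic_lengths <- function(annotation, genome_length) {
  ann <- validate_annotation(annotation, genome_length)
  if (nrow(ann) < 2L) stop("need at least two features", call. = FALSE)
  if (is.unsorted(ann$start)) {
    stop("annotation is not ordered by start coordinate; sort it with ",
         "dplyr::arrange(start) first", call. = FALSE)
  }
  nxt_start <- c(ann$start[-1L], ann$start[1L] + genome_length)
  tibble(
    gene = ann$gene,
    next_gene = c(ann$gene[-1L], ann$gene[1L]),
    spacer = as.integer(nxt_start - ann$end - 1L)
  )
}

#' Count genes per strand
#'
#' Tallies gene features (the control region is non-coding and excluded) on
#' the majority (F) and minority (R) strands.
#'
#' @param annotation Annotation tibble.
#' @return A tibble with columns `strand` ("F", "R") and `n`.
#' @export
strand_census <- function(annotation) {
  ann <- validate_annotation(annotation)
  genes <- dplyr::filter(ann, .data$category != "control")
  tibble(
    strand = c("F", "R"),
    n = c(sum(genes$strand == "F"), sum(genes$strand == "R"))
  )
}

# 1-based genome positions covered by a feature, in genome (F-strand) order
feature_positions <- function(start, end, genome_length) {
  if (end >= start) start:end else c(start:genome_length, 1:end)
}

#' Extract the strand-corrected sequence of a feature
#'
#' Returns the coding-strand sequence of a 1-based inclusive range: the
#' stored subsequence for F-strand features, its reverse complement for
#' R-strand features. Ranges with `end < start` wrap the origin, which is
#' only permitted on circular genomes.
#'
#' @param genome A [mito_genome()] object.
#' @param start,end 1-based inclusive coordinates.
#' @param strand "F" or "R".
#' @return A DNA string.
#' @examples
#' g <- mito_genome("AAACCC")
#' extract_feature_sequence(g, 5, 2) # wraps: "CCAA"
#' @export
extract_feature_sequence <- function(genome, start, end, strand = "F") {
  stopifnot(inherits(genome, "mito_genome"), strand %in% c("F", "R"))
  L <- genome$length
  if (start < 1L || end < 1L || start > L || end > L) {
    stop("coordinates out of range 1..", L, call. = FALSE)
  }
  if (end >= start) {
    s <- substr(genome$sequence, start, end)
  } else {
    if (!genome$circular) {
      stop("feature wraps the origin but the genome is not circular", call. = FALSE)
    }
    s <- paste0(substr(genome$sequence, start, L), substr(genome$sequence, 1L, end))
  }
  if (strand == "R") dna_revcomp(s) else s
}

#' Strand-corrected sequences of every feature
#'
#' @param genome A [mito_genome()] object.
#' @param annotation Annotation tibble.
#' @return The annotation with `size` and `seq` columns appended.
#' @export
feature_sequences <- function(genome, annotation) {
  ann <- feature_lengths(validate_annotation(annotation, genome$length),
                         genome$length)
  ann$seq <- purrr::pmap_chr(
    list(ann$start, ann$end, ann$strand),
    function(s, e, st) extract_feature_sequence(genome, s, e, st)
  )
  ann
}
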