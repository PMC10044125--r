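# Signed gene orders and rearrangement detection.
#
# A gene order is a tibble with columns `gene` and `strand`, one row per
# gene, in position order along the majority strand. Circular orders are
# linearized at a shared anchor gene before comparison.

#' Extract the gene order of an annotation
#'
#' Genes are ordered by start coordinate along the majority strand; the
#' non-coding control region is excluded. A tie on start coordinates is an
#' error, since the order would be ambiguous.
#'
#' @param annotation Annotation tibble.
#' @return A tibble with columns `gene` and `strand`.
#' @export
extract_gene_order <- function(annotation) {
  ann <- validate_annotation(annotation)
  genes <- dplyr::filter(ann, .data$category != "control")
  if (anyDuplicated(genes$start)) {
    dup <- genes$start[duplicated(genes$start)][1L]
    stop("cannot order genes: tie on start coordinate ", dup, call. = FALSE)
  }
  genes <- dplyr::arrange(genes, .data$start)
  dplyr::select(genes, "gene", "strand")
}

#' The ancestral insect mitochondrial gene order
#'
#' The putative ancestral arthropod/insect arrangement (as in *Drosophila*),
#' in which the tRNA cluster upstream of nad2 runs trnI–trnQ–trnM. Many
#' Lepidoptera, including the box tree moth, instead carry the derived
#' trnM–trnI–trnQ arrangement produced by a trnM translocation.
#'
#' @return A 37-row gene-order tibble (13 PCGs, 22 tRNAs, 2 rRNAs).
#' @export
ancestral_insect_order <- function() {
  entries <- c(
    "trnI" = "F", "trnQ" = "R", "trnM" = "F", "nad2" = "F", "trnW" = "F",
    "trnC" = "R", "trnY" = "R", "cox1" = "F", "trnL2" = "F", "cox2" = "F",
    "trnK" = "F", "trnD" = "F", "atp8" = "F", "atp6" = "F", "cox3" = "F",
    "trnG" = "F", "nad3" = "F", "trnA" = "F", "trnR" = "F", "trnN" = "F",
    "trnS1" = "F", "trnE" = "F", "trnF" = "R", "nad5" = "R", "trnH" = "R",
    "nad4" = "R", "nad4L" = "R", "trnT" = "F", "trnP" = "R", "nad6" = "F",
    "cob" = "F", "trnS2" = "F", "nad1" = "R", "trnL1" = "R", "rrnL" = "R",
    "trnV" = "R", "rrnS" = "R"
  )
  tibble(gene = names(entries), strand = unname(entries))
}

rotate_to_anchor <- function(order, anchor) {
  i <- match(anchor, order$gene)
  if (is.na(i)) stop("anchor gene '", anchor, "' not present in order", call. = FALSE)
  if (i == 1L) return(order)
  dplyr::bind_rows(order[i:nrow(order), ], order[1:(i - 1L), ])
}

# longest common subsequence of two character vectors (names unique within
# each vector here, but the DP is general); returns the common subsequence
lcs_names <- function(a, b) {
  n <- length(a); m <- length(b)
  if (n == 0L || m == 0L) return(character(0))
  d <- matrix(0L, n + 1L, m + 1L)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      d[i + 1L, j + 1L] <- if (a[i] == b[j]) d[i, j] + 1L else
        max(d[i, j + 1L], d[i + 1L, j])
    }
  }
  out <- character(d[n + 1L, m + 1L])
  i <- n; j <- m; k <- length(out)
  while (i > 0L && j > 0L) {
    if (a[i] == b[j]) {
      out[k] <- a[i]; k <- k - 1L; i <- i - 1L; j <- j - 1L
    } else if (d[i, j + 1L] >= d[i + 1L, j]) {
      i <- i - 1L
    } else {
      j <- j - 1L
    }
  }
  out
}

#' Compare two circular gene orders
#'
#' Both orders are alias-normalized, linearized at a shared anchor gene and
#' compared by a longest common subsequence over gene names: the moved-gene
#' set is the complement of the LCS, which is a minimum set of genes whose
#' relocation explains the difference. Strand signs are carried along and,
#' in strict mode, genes whose strand differs between the orders are also
#' reported; the default compares names only, since a pure translocation
#' (the typical tRNA rearrangement) does not flip strands.
#'
#' @param observed,reference Gene-order tibbles (columns `gene`, `strand`).
#' @param anchor Gene at which both circular orders are linearized.
#' @param strict Also flag strand flips?
#' @return An object of class `gene_order_diff` with fields `moved_genes`,
#'   `identical`, `lcs`, `strand_flips`, `anchor`, `observed`, `reference`.
#' @examples
#' obs <- tibble::tibble(gene = c("cox1", "trnM", "trnI", "trnQ"),
#'                       strand = c("F", "F", "F", "R"))
#' ref <- tibble::tibble(gene = c("cox1", "trnI", "trnQ", "trnM"),
#'                       strand = c("F", "F", "R", "F"))
#' compare_orders(obs, ref)$moved_genes # "trnM"
#' @export
compare_orders <- function(observed, reference, anchor = "cox1", strict = FALSE) {
  norm <- function(x) {
    x <- as_tibble(x)
    stopifnot(all(c("gene", "strand") %in% names(x)))
    dplyr::mutate(x, gene = normalize_gene_names(.data$gene))
  }
  obs <- norm(observed); ref <- norm(reference)
  if (anyDuplicated(obs$gene) || anyDuplicated(ref$gene)) {
    stop("gene names must be unique within an order", call. = FALSE)
  }
  extra <- setdiff(obs$gene, ref$gene)
  missing <- setdiff(ref$gene, obs$gene)
  if (length(extra) > 0L || length(missing) > 0L) {
    stop("gene sets differ; only in observed: {",
         paste(extra, collapse = ", "), "}, only in reference: {",
         paste(missing, collapse = ", "), "}", call. = FALSE)
  }
  obs <- rotate_to_anchor(obs, normalize_gene_names(anchor))
  ref <- rotate_to_anchor(ref, normalize_gene_names(anchor))
  lcs <- lcs_names(obs$gene, ref$gene)
  moved <- setdiff(obs$gene, lcs)
  flips <- if (strict) {
    obs$gene[obs$strand != ref$strand[match(obs$gene, ref$gene)]]
  } else {
    character(0)
  }
  structure(
    list(moved_genes = moved, identical = length(moved) == 0L, lcs = lcs,
         strand_flips = flips, anchor = anchor,
         observed = obs, reference = ref),
    class = "gene_order_diff"
  )
}

#' @export
print.gene_order_diff <- function(x, ...) {
  if (x$identical) {
    cat("<gene_order_diff> orders identical (", nrow(x$observed), " genes)\n", sep = "")
  } else {
    cat(sprintf("<gene_order_diff> %d moved gene(s): %s (anchor %s)\n",
                length(x$moved_genes), paste(x$moved_genes, collapse = ", "),
                x$anchor))
  }
  if (length(x$strand_flips) > 0L) {
    cat("  strand flips:", paste(x$strand_flips, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Format a gene order as a signed one-line string
#'
#' R-strand genes are prefixed with `-`.
#'
#' @param order Gene-order tibble.
#' @return A single string.
#' @examples
#' format_gene_order(ancestral_insect_order())
#' @export
format_gene_order <- function(order) {
  paste(ifelse(order$strand == "R", paste0("-", order$gene), order$gene),
        collapse = " ")
}
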