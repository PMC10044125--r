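# broom-style tidiers for the package's result objects.

#' Tidy a gene-order comparison
#'
#' @param x A `gene_order_diff` from [compare_orders()].
#' @param ... Unused.
#' @return A tibble with one row per gene: positions in both linearized
#'   orders, strands, and whether the gene is in the moved set.
#' @export
tidy.gene_order_diff <- function(x, ...) {
  obs <- x$observed
  ref <- x$reference
  tibble(
    gene = obs$gene,
    position_observed = seq_len(nrow(obs)),
    position_reference = match(obs$gene, ref$gene),
    strand_observed = obs$strand,
    strand_reference = ref$strand[match(obs$gene, ref$gene)],
    moved = obs$gene %in% x$moved_genes
  )
}

#' @rdname tidy.gene_order_diff
#' @return For `glance()`: a one-row summary tibble.
#' @export
glance.gene_order_diff <- function(x, ...) {
  tibble(
    n_genes = nrow(x$observed),
    n_moved = length(x$moved_genes),
    identical = x$identical,
    lcs_length = length(x$lcs),
    n_strand_flips = length(x$strand_flips),
    anchor = x$anchor
  )
}

#' Tidy a simulated mitogenome
#'
#' @param x A `mito_sim` from [generate_mitogenome()].
#' @param ... Unused.
#' @return The realized annotation tibble with feature sizes.
#' @export
tidy.mito_sim <- function(x, ...) {
  feature_lengths(x$annotation, x$genome$length)
}

#' @rdname tidy.mito_sim
#' @return For `glance()`: a one-row summary of the emitted genome.
#' @export
glance.mito_sim <- function(x, ...) {
  b <- count_bases(x$genome$sequence)
  tab <- table(factor(x$annotation$category,
                      levels = c("PCG", "tRNA", "rRNA", "control")))
  tibble(
    genome_length = x$genome$length,
    n_features = nrow(x$annotation),
    n_pcg = as.integer(tab[["PCG"]]),
    n_trna = as.integer(tab[["tRNA"]]),
    n_rrna = as.integer(tab[["rRNA"]]),
    at_pct = at_content(b),
    at_skew = at_skew(b),
    gc_skew = gc_skew(b)
  )
}
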