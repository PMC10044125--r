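# ggplot2 views of the result tables.

#' Plot relative synonymous codon usage
#'
#' Stacked RSCU bars per amino-acid class, the conventional codon-bias
#' figure of mitogenome papers. Stop codons are dropped by default.
#'
#' @param object A `mito_rscu` tibble from [compute_rscu()].
#' @param include_stops Show the stop family?
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mito_rscu <- function(object, include_stops = FALSE, ...) {
  df <- as_tibble(object)
  if (!include_stops) df <- dplyr::filter(df, .data$aa != "*")
  df <- dplyr::mutate(df, codon = codon_to_rna(.data$codon))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aa_class, y = .data$rscu,
                                   fill = .data$codon)) +
    ggplot2::geom_col(colour = "grey30", linewidth = 0.2, width = 0.8) +
    ggplot2::guides(fill = "none") +
    ggplot2::labs(x = NULL, y = "RSCU") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' Plot per-region composition
#'
#' AT/GC content bars with skews annotated, one panel per statistic.
#'
#' @param object A `mito_composition` tibble from [composition_table()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mito_composition <- function(object, ...) {
  df <- as_tibble(object) %>%
    dplyr::select("region", "at_pct", "gc_pct", "at_skew", "gc_skew") %>%
    tidyr::pivot_longer(-"region", names_to = "statistic") %>%
    dplyr::mutate(region = factor(.data$region, levels = .region_levels))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$region, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::facet_wrap(~statistic, scales = "free_y") +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot control-region hits
#'
#' Draws each detected element as a horizontal segment along the control
#' region, coloured by kind (motif, homopolymers, microsatellite, tandem
#' repeats).
#'
#' @param object A `cr_report` tibble from [control_region_report()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cr_report <- function(object, ...) {
  df <- as_tibble(object)
  df$label <- sprintf("%s (%s)", df$kind, df$unit)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$start, xend = .data$end,
                                   y = .data$label, yend = .data$label,
                                   colour = .data$kind)) +
    ggplot2::geom_segment(linewidth = 4) +
    ggplot2::labs(x = "position in control region (bp)", y = NULL,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot amino-acid usage totals
#'
#' @param totals Tibble from [amino_acid_totals()].
#' @return A ggplot object.
#' @export
plot_amino_acid_totals <- function(totals) {
  df <- dplyr::mutate(totals,
                      aa_class = stats::reorder(.data$aa_class, -.data$count))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$aa_class, y = .data$count)) +
    ggplot2::geom_col(fill = "darkorange") +
    ggplot2::labs(x = NULL, y = "codons") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}
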