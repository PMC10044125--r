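# End-to-end characterization report and the command-line front end.

#' Characterize an annotated mitogenome
#'
#' Runs the whole characterization on a genome + feature table and writes
#' the summary artifacts a mitogenome paper tabulates: the annotation
#' summary (sizes, intergenic spacers, observed start/stop codons), the
#' per-region composition/skew table, the codon-usage/RSCU table, the
#' gene-order comparison against a reference order, and the control-region
#' element report. Outputs are deterministic for identical inputs; run
#' metadata (package version, parameters, timestamp) goes to a separate log
#' file. On any error all files written so far are removed.
#'
#' @param genome A [mito_genome()] object, or a path to a FASTA file.
#' @param annotation Annotation tibble, or a path to a feature table.
#' @param out_dir Output directory (created if needed).
#' @param json Also emit each table as JSON?
#' @param anchor Linearization anchor for the gene-order comparison.
#' @param reference Reference gene order (default: ancestral insect order).
#' @param cr_config Control-region scan thresholds ([cr_scan_defaults()]).
#' @return Invisibly, a named list of the result tables.
#' @export
mito_report <- function(genome, annotation, out_dir, json = FALSE,
                        anchor = "cox1", reference = ancestral_insect_order(),
                        cr_config = cr_scan_defaults()) {
  if (is.character(genome)) genome <- read_genome_fasta(genome)
  if (is.character(annotation)) {
    annotation <- read_feature_table(annotation, genome_length = genome$length)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  written <- character(0)
  emit <- function(x, name) {
    tsv <- file.path(out_dir, paste0(name, ".tsv"))
    written <<- c(written, tsv)
    if (name == "composition") {
      write_composition_tsv(x, tsv)
    } else if (name == "codon_usage") {
      write_codon_usage_tsv(x, tsv)
    } else {
      readr::write_tsv(as_tibble(x), tsv, progress = FALSE)
    }
    if (json) {
      js <- file.path(out_dir, paste0(name, ".json"))
      written <<- c(written, js)
      jsonlite::write_json(as_tibble(x), js, dataframe = "columns",
                           digits = NA, pretty = TRUE)
    }
  }

  tryCatch({
    ann <- validate_annotation(annotation, genome$length)
    cu <- codon_usage(genome, ann)
    summary_tbl <- feature_lengths(ann, genome$length) %>%
      dplyr::left_join(intergenic_lengths(ann, genome$length),
                       by = "gene") %>%
      dplyr::left_join(cu$genes, by = "gene", suffix = c("", "_observed")) %>%
      dplyr::select("gene", "category", "strand", "start", "end", "size",
                    intergenic = "spacer", "anticodon",
                    dplyr::any_of(c("start_codon_observed", "start_class",
                                    "stop_status")))
    diff <- compare_orders(extract_gene_order(ann), reference, anchor = anchor)
    cr <- control_region_report(genome, ann, cr_config)
    results <- list(
      annotation_summary = summary_tbl,
      composition = composition_table(genome, ann),
      codon_usage = cu$rscu,
      gene_order_diff = tidy(diff),
      control_region_hits = as_tibble(cr)
    )
    for (nm in names(results)) emit(results[[nm]], nm)

    log_file <- file.path(out_dir, "run_info.txt")
    written <<- c(written, log_file)
    readr::write_lines(c(
      paste0("mitochar version: ", as.character(utils::packageVersion("mitochar"))),
      paste0("R version: ", R.version.string),
      paste0("genome: ", genome$id, " (", genome$length, " bp)"),
      paste0("anchor: ", anchor),
      paste0("cr thresholds: polyT>=", cr_config$polyt_min,
             " polyA>=", cr_config$polya_min,
             " microsat ", cr_config$microsat_unit, ">=",
             cr_config$microsat_min_copies,
             " tandem unit>=", cr_config$tandem_min_unit,
             " copies>=", cr_config$tandem_min_copies),
      paste0("timestamp: ", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z"))
    ), log_file)
    invisible(results)
  }, error = function(e) {
    unlink(written)
    stop(e)
  })
}

cli_subcommands <- c("summarize", "composition", "codon-usage", "gene-order",
                     "control-region", "simulate")

#' Command-line entry point
#'
#' Drives the package from a shell. Subcommands: `summarize` (all report
#' tables), `composition`, `codon-usage`, `gene-order`, `control-region`
#' (each a single table), and `simulate` (emit a synthetic mitogenome with
#' its manifest). A thin wrapper script calling this function is installed
#' under `exec/mitochar`.
#'
#' @param args Character vector of command-line arguments, e.g.
#'   `c("summarize", "--fasta", "g.fa", "--features", "t.tsv", "--out", "d")`.
#' @return Exit status, invisibly: 0 on success, 1 on error.
#' @export
mito_cli <- function(args = commandArgs(trailingOnly = TRUE)) {
  usage <- paste0("usage: mitochar <", paste(cli_subcommands, collapse = "|"),
                  "> [options]")
  if (length(args) == 0L || !args[1L] %in% cli_subcommands) {
    message(usage)
    return(invisible(1L))
  }
  sub <- args[1L]
  rest <- args[-1L]
  run <- function() {
    if (sub == "simulate") {
      opts <- optparse::parse_args(optparse::OptionParser(
        option_list = list(
          optparse::make_option("--profile", default = "perspectalis"),
          optparse::make_option("--seed", type = "integer", default = 1L),
          optparse::make_option("--out", default = NULL)
        )), args = rest)
      if (is.null(opts$out)) stop("--out is required", call. = FALSE)
      if (opts$profile != "perspectalis") {
        stop("unknown profile '", opts$profile, "'", call. = FALSE)
      }
      sim <- generate_mitogenome(perspectalis_profile(), seed = opts$seed)
      write_sim(sim, opts$out)
      return(invisible(NULL))
    }
    opts <- optparse::parse_args(optparse::OptionParser(
      option_list = list(
        optparse::make_option("--fasta", default = NULL),
        optparse::make_option("--features", default = NULL),
        optparse::make_option("--out", default = NULL),
        optparse::make_option("--json", action = "store_true", default = FALSE),
        optparse::make_option("--anchor", default = "cox1"),
        optparse::make_option("--min-unit", dest = "min_unit",
                              type = "integer", default = 5L),
        optparse::make_option("--min-copies", dest = "min_copies",
                              type = "integer", default = 2L)
      )), args = rest)
    for (req in c("fasta", "features", "out")) {
      if (is.null(opts[[req]])) stop("--", req, " is required", call. = FALSE)
    }
    for (f in c(opts$fasta, opts$features)) {
      if (!file.exists(f)) stop("input not found: ", f, call. = FALSE)
    }
    cfg <- cr_scan_defaults(tandem_min_unit = opts$min_unit,
                            tandem_min_copies = opts$min_copies)
    genome <- read_genome_fasta(opts$fasta)
    ann <- read_feature_table(opts$features, genome_length = genome$length)
    if (sub == "summarize") {
      mito_report(genome, ann, opts$out, json = opts$json,
                  anchor = opts$anchor, cr_config = cfg)
      return(invisible(NULL))
    }
    dir.create(opts$out, recursive = TRUE, showWarnings = FALSE)
    emit <- function(x, name, writer = NULL) {
      tsv <- file.path(opts$out, paste0(name, ".tsv"))
      if (is.null(writer)) {
        readr::write_tsv(as_tibble(x), tsv, progress = FALSE)
      } else {
        writer(x, tsv)
      }
      if (opts$json) {
        jsonlite::write_json(as_tibble(x),
                             file.path(opts$out, paste0(name, ".json")),
                             dataframe = "columns", digits = NA, pretty = TRUE)
      }
    }
    switch(sub,
      "composition" = emit(composition_table(genome, ann), "composition",
                           write_composition_tsv),
      "codon-usage" = emit(codon_usage(genome, ann)$rscu, "codon_usage",
                           write_codon_usage_tsv),
      "gene-order" = emit(tidy(compare_orders(extract_gene_order(ann),
                                              ancestral_insect_order(),
                                              anchor = opts$anchor)),
                          "gene_order_diff"),
      "control-region" = emit(control_region_report(genome, ann, cfg),
                              "control_region_hits")
    )
    invisible(NULL)
  }
  status <- tryCatch({
    run()
    0L
  }, error = function(e) {
    message("mitochar ", sub, ": ", conditionMessage(e))
    1L
  })
  invisible(status)
}
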