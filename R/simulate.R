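# Seeded generator of synthetic circular mitogenomes with a ground-truth
# manifest, so every analysis stage can be validated without downloads.
#
# Strategy: sample each region i.i.d. from its region-class base
# distribution, then overwrite the discrete features at fixed positions
# (planned start codons, stop codons / incomplete-stop trailing bases,
# planted control-region elements). Discrete features therefore have exact
# ground truth while the bulk sequence stays stochastic. The manifest is
# computed from the *realized* sequence and verified before return.

#' Configuration for the synthetic-mitogenome generator
#'
#' @param features Annotation tibble giving the layout: gene, category,
#'   strand, start, end, anticodon, plus `start_codon` and `stop_plan`
#'   columns for PCGs. `stop_plan` is one of "TAA", "TAG" (complete stop),
#'   "T", "TA" (incomplete stop realized as trailing bases) and must be
#'   consistent with the feature length modulo 3.
#' @param region_probs Named list of base-probability vectors (names A, C,
#'   G, T summing to 1) for classes `PCG`, `tRNA`, `rRNA`, `control`,
#'   `intergenic`.
#' @param cr_elements Tibble of elements to plant in the control region:
#'   columns `kind` ("motif", "homopolymer", "microsatellite"), `unit`,
#'   `copies`.
#' @param genome_id Identifier for the emitted FASTA record.
#' @param seed Default seed used by [generate_mitogenome()].
#' @param scan_config [cr_scan_defaults()] configuration under which the
#'   control region is guaranteed to contain exactly the planted elements.
#' @return A list of class `mito_sim_config`.
#' @export
mito_sim_config <- function(features, region_probs, cr_elements,
                            genome_id = "synthetic_mitogenome", seed = 1L,
                            scan_config = cr_scan_defaults()) {
  features <- validate_annotation(features)
  stopifnot(all(c("PCG", "tRNA", "rRNA", "control", "intergenic") %in%
                  names(region_probs)))
  for (p in region_probs) {
    stopifnot(all(c("A", "C", "G", "T") %in% names(p)),
              abs(sum(p) - 1) < 1e-6, all(p >= 0))
  }
  structure(
    list(features = features, region_probs = region_probs,
         cr_elements = as_tibble(cr_elements), genome_id = genome_id,
         seed = as.integer(seed), scan_config = scan_config),
    class = "mito_sim_config"
  )
}

#' @export
print.mito_sim_config <- function(x, ...) {
  cat(sprintf("<mito_sim_config> %d features, %d planted CR element(s), seed %d\n",
              nrow(x$features), nrow(x$cr_elements), x$seed))
  invisible(x)
}

#' Generator profile emulating the box tree moth mitogenome
#'
#' A configuration whose gene order, strands, coordinates, anticodons and
#' start codons follow the published annotation of the *Cydalima
#' perspectalis* mitogenome (15,180 bp; see [cydalima_annotation()]),
#' whose region base compositions follow its published composition table,
#' and whose 288 bp control region plants the four elements reported for
#' this species: an ATAGG(A) motif followed by a 17 bp poly-T stretch, an
#' (AT)14 microsatellite, and a 10 bp poly-A stretch in front of trnM.
#' Published stop codons inconsistent with the annotated gene length modulo
#' 3 (single-T stops on lengths divisible by three) are planned as complete
#' TAA stops, the only stop realizable at those coordinates.
#'
#' @param seed Default seed stored in the configuration.
#' @return A `mito_sim_config`.
#' @export
perspectalis_profile <- function(seed = 1L) {
  ann <- cydalima_annotation()
  len <- feature_length(ann$start, ann$end)
  stop_plan <- dplyr::case_when(
    ann$category != "PCG" ~ NA_character_,
    len %% 3L == 0L ~ "TAA",
    len %% 3L == 1L ~ "T",
    TRUE ~ "TA"
  )
  # keep the published complete stops where they are feasible
  keep <- ann$category == "PCG" & !is.na(ann$stop_codon) &
    ann$stop_codon %in% c("TAA", "TAG") & len %% 3L == 0L
  stop_plan[keep] <- ann$stop_codon[keep]
  features <- dplyr::mutate(ann, stop_plan = stop_plan)
  region_probs <- list(
    PCG = c(A = 0.341, C = 0.097, G = 0.107, T = 0.455),
    tRNA = c(A = 0.414, C = 0.075, G = 0.109, T = 0.403) / 1.001,
    rRNA = c(A = 0.444, C = 0.051, G = 0.104, T = 0.401),
    control = c(A = 0.476, C = 0.024, G = 0.014, T = 0.486),
    intergenic = c(A = 0.399, C = 0.114, G = 0.077, T = 0.410)
  )
  cr_elements <- tibble(
    kind = c("motif", "homopolymer", "microsatellite", "homopolymer"),
    unit = c("ATAGGA", "T", "AT", "A"),
    copies = c(1L, 17L, 14L, 10L)
  )
  mito_sim_config(features, region_probs, cr_elements,
                  genome_id = "synthetic_perspectalis_like", seed = seed)
}

sample_bases <- function(n, probs) {
  if (n == 0L) return(character(0))
  sample(names(probs), n, replace = TRUE, prob = probs)
}

# sample n sense codons (rejecting TAA/TAG) from per-base probabilities
sample_sense_codons <- function(n, probs) {
  if (n == 0L) return(character(0))
  draw <- function(k) {
    paste0(sample_bases(k, probs), sample_bases(k, probs), sample_bases(k, probs))
  }
  codons <- draw(n)
  repeat {
    bad <- which(codons %in% c("TAA", "TAG"))
    if (length(bad) == 0L) break
    codons[bad] <- draw(length(bad))
  }
  codons
}

# genome positions of coding positions `idx` of a feature (strand-aware)
coding_positions <- function(start, end, strand, L, idx = NULL) {
  pos <- feature_positions(start, end, L)
  if (strand == "R") pos <- rev(pos)
  if (is.null(idx)) pos else pos[idx]
}

# write a coding-space segment into the genome character vector
write_coding <- function(x, start, end, strand, L, coding_start, segment) {
  chars <- seq_chars(segment)
  idx <- coding_start:(coding_start + length(chars) - 1L)
  gpos <- coding_positions(start, end, strand, L, idx)
  x[gpos] <- if (strand == "R") dna_complement(chars) else chars
  x
}

# deterministic control-region layout: planted elements separated by
# background gaps, each flanked by guard bases so runs/arrays cannot extend
plan_cr_layout <- function(elements, cr_len) {
  el <- dplyr::mutate(
    as_tibble(elements),
    string = dplyr::case_when(
      .data$kind == "motif" ~ .data$unit,
      .data$kind %in% c("homopolymer", "microsatellite") ~
        strrep(.data$unit, .data$copies),
      TRUE ~ NA_character_
    )
  )
  if (anyNA(el$string)) {
    stop("unsupported planted element kind: ",
         paste(unique(el$kind[is.na(el$string)]), collapse = ", "), call. = FALSE)
  }
  # guard bases stop runs/arrays from extending into the background: the
  # left neighbour must differ from the unit's last base, the right
  # neighbour from its first (A/T preferred to keep the region AT-rich)
  pick_guard <- function(avoid) {
    for (b in c("A", "T", "C")) if (b != avoid) return(b)
  }
  el$guard_left <- purrr::map_chr(el$string, function(s) {
    pick_guard(substr(s, nchar(s), nchar(s)))
  })
  el$guard_right <- purrr::map_chr(el$string, function(s) {
    pick_guard(substr(s, 1L, 1L))
  })
  need <- sum(nchar(el$string)) + 2L * nrow(el)
  if (need > cr_len) {
    stop(sprintf("planted elements need %d bp but the control region is %d bp",
                 need, cr_len), call. = FALSE)
  }
  gap <- (cr_len - need) %/% (nrow(el) + 1L)
  pos <- integer(nrow(el))
  cursor <- gap + 1L
  for (i in seq_len(nrow(el))) {
    pos[i] <- cursor + 1L # element starts after its left guard
    cursor <- cursor + 2L + nchar(el$string[i]) + gap
  }
  el$start <- pos
  el$end <- pos + nchar(el$string) - 1L
  el
}

# greedily mutate the control-region background until the scanners report
# exactly the planted elements
clean_cr_background <- function(cr, planted, config, max_iter = 500L) {
  protected <- unlist(purrr::map2(planted$start - 1L, planted$end + 1L, seq))
  key <- function(h) paste(h$kind, h$start, h$end, h$unit, h$copies)
  planted_keys <- key(planted)
  for (iter in seq_len(max_iter)) {
    hits <- scan_cr_sequence(paste(cr, collapse = ""), config)
    extra <- hits[!key(hits) %in% planted_keys, ]
    if (nrow(extra) == 0L) return(cr)
    h <- extra[1L, ]
    span <- setdiff(h$start:h$end, protected)
    if (length(span) == 0L) {
      stop("cannot clean control-region background: chance element at ",
           h$start, "..", h$end, " overlaps planted elements", call. = FALSE)
    }
    # middle-out over the span, A/T substitutions first so the cleanup does
    # not erode the AT-richness of the region
    span <- span[order(abs(seq_along(span) - (length(span) + 1) / 2))]
    moves <- expand.grid(p = span, b = c("A", "T", "C", "G"),
                         stringsAsFactors = FALSE)
    moves <- moves[order(match(moves$b, c("A", "T", "C", "G"))), ]
    improved <- FALSE
    for (k in seq_len(nrow(moves))) {
      p <- moves$p[k]; b <- moves$b[k]
      if (b == cr[p]) next
      cand <- cr
      cand[p] <- b
      cand_hits <- scan_cr_sequence(paste(cand, collapse = ""), config)
      cand_extra <- cand_hits[!key(cand_hits) %in% planted_keys, ]
      better <- nrow(cand_extra) < nrow(extra) ||
        (nrow(cand_extra) == nrow(extra) &&
           sum(cand_extra$end - cand_extra$start) < sum(extra$end - extra$start))
      if (better) {
        cr <- cand
        improved <- TRUE
        break
      }
    }
    if (!improved) {
      stop("cannot clean control-region background: chance element at ",
           h$start, "..", h$end, " resists point mutation", call. = FALSE)
    }
  }
  stop("control-region cleanup did not converge", call. = FALSE)
}

count_chars <- function(s) {
  x <- seq_chars(s)
  tibble(A = sum(x == "A"), C = sum(x == "C"), G = sum(x == "G"),
         T = sum(x == "T"), other = sum(!x %in% c("A", "C", "G", "T")),
         total = length(x))
}

#' Generate a synthetic circular mitogenome with ground truth
#'
#' Emits a genome whose layout follows the configuration exactly: PCGs begin
#' with their planned start codons and end with their planned (complete or
#' incomplete) stops, annotated overlaps are realized as negative spacers,
#' and the control region contains exactly the planted elements under the
#' configuration's scan thresholds (chance look-alikes in the sampled
#' background are broken by point mutations before emission). The returned
#' manifest is derived from the realized sequence and checked against the
#' plan; an infeasible configuration raises an error naming the constraint.
#'
#' @param config A `mito_sim_config`, e.g. [perspectalis_profile()].
#' @param seed Integer seed; defaults to the seed stored in the
#'   configuration. The generator touches no global RNG state.
#' @return An object of class `mito_sim`: a list with elements `genome`
#'   (a [mito_genome()]), `annotation` (realized annotation tibble) and
#'   `manifest` (list with `genome_length`, `region_base_counts`,
#'   `codon_counts`, `codon_counts_all`, `gene_starts_stops`, `cr_hits`,
#'   `gene_order`).
#' @examples
#' \donttest{
#' sim <- generate_mitogenome(perspectalis_profile(), seed = 42)
#' sim$genome
#' }
#' @export
generate_mitogenome <- function(config = perspectalis_profile(),
                                seed = config$seed) {
  stopifnot(inherits(config, "mito_sim_config"))
  withr::with_seed(as.integer(seed), generate_mitogenome_impl(config))
}

generate_mitogenome_impl <- function(config) {
  ann <- config$features
  probs <- config$region_probs
  L <- max(ann$end)
  ann <- validate_annotation(ann, L)
  len <- feature_length(ann$start, ann$end, L)

  # feasibility of stop plans against length mod 3
  pcg <- which(ann$category == "PCG")
  if (!"stop_plan" %in% names(ann)) stop("config features lack stop_plan", call. = FALSE)
  for (i in pcg) {
    plan <- ann$stop_plan[i]
    r <- len[i] %% 3L
    ok <- (plan %in% c("TAA", "TAG") && r == 0L) ||
      (plan == "T" && r == 1L) || (plan == "TA" && r == 2L)
    if (!isTRUE(ok)) {
      stop(sprintf("gene %s: stop plan '%s' infeasible for length %d (mod 3 = %d)",
                   ann$gene[i], plan, len[i], r), call. = FALSE)
    }
    if (is.na(ann$start_codon[i])) {
      stop("gene ", ann$gene[i], ": PCG lacks a planned start codon", call. = FALSE)
    }
  }

  # 1. intergenic background
  x <- sample_bases(L, probs$intergenic)

  # 2. RNA features, then PCG bodies (later writes win; the critical pass
  #    below re-asserts starts/stops clobbered by annotated overlaps)
  for (i in which(ann$category %in% c("tRNA", "rRNA"))) {
    body <- paste(sample_bases(len[i], probs[[ann$category[i]]]), collapse = "")
    x <- write_coding(x, ann$start[i], ann$end[i], ann$strand[i], L, 1L, body)
  }
  for (i in pcg) {
    trailing <- if (ann$stop_plan[i] %in% c("T", "TA")) ann$stop_plan[i] else ""
    terminal <- if (trailing == "") ann$stop_plan[i] else ""
    n_interior <- (len[i] - nchar(trailing)) %/% 3L - 1L - (terminal != "")
    if (n_interior < 0L) {
      stop("gene ", ann$gene[i], " too short for its start/stop plan", call. = FALSE)
    }
    cds <- paste0(ann$start_codon[i],
                  paste(sample_sense_codons(n_interior, probs$PCG), collapse = ""),
                  terminal, trailing)
    stopifnot(nchar(cds) == len[i])
    x <- write_coding(x, ann$start[i], ann$end[i], ann$strand[i], L, 1L, cds)
  }

  # 3. critical pass: re-assert every PCG start and stop, detecting
  #    irreconcilable overlaps between critical elements
  crit <- rep(NA_character_, L)
  assert_segment <- function(i, coding_start, segment) {
    chars <- seq_chars(segment)
    idx <- coding_start:(coding_start + length(chars) - 1L)
    gpos <- coding_positions(ann$start[i], ann$end[i], ann$strand[i], L, idx)
    gchars <- if (ann$strand[i] == "R") dna_complement(chars) else chars
    clash <- !is.na(crit[gpos]) & crit[gpos] != gchars
    if (any(clash)) {
      stop(sprintf("infeasible overlap: start/stop of %s collides at position %d",
                   ann$gene[i], gpos[which(clash)[1L]]), call. = FALSE)
    }
    crit[gpos] <<- gchars
    x[gpos] <<- gchars
  }
  for (i in pcg) {
    assert_segment(i, 1L, ann$start_codon[i])
    tail_seq <- ann$stop_plan[i] # "TAA"/"TAG" terminal codon or "T"/"TA" trailing
    assert_segment(i, len[i] - nchar(tail_seq) + 1L, tail_seq)
  }

  # 4. control region: background, planted elements, cleanup
  cr_row <- which(ann$category == "control")
  planted <- hit_tibble()
  if (length(cr_row) == 1L) {
    i <- cr_row
    layout <- plan_cr_layout(config$cr_elements, len[i])
    cr <- sample_bases(len[i], probs$control)
    for (j in seq_len(nrow(layout))) {
      span <- layout$start[j]:layout$end[j]
      cr[span] <- seq_chars(layout$string[j])
      cr[layout$start[j] - 1L] <- layout$guard_left[j]
      if (layout$end[j] + 1L <= len[i]) cr[layout$end[j] + 1L] <- layout$guard_right[j]
    }
    planted <- hit_tibble(
      kind = layout$kind, start = layout$start, end = layout$end,
      unit = layout$unit, copies = layout$copies
    )
    # the motif scanner reports the bare motif extended by its tail base, so
    # the planted "ATAGGA" is expected back as unit ATAGGA over its span
    cr <- clean_cr_background(cr, planted, config$scan_config)
    x <- write_coding(x, ann$start[i], ann$end[i], ann$strand[i], L, 1L,
                      paste(cr, collapse = ""))
  } else if (nrow(config$cr_elements) > 0L) {
    stop("cr_elements configured but features contain no control region", call. = FALSE)
  }

  genome <- mito_genome(paste(x, collapse = ""), id = config$genome_id,
                        circular = TRUE)

  # 5. realized annotation and manifest, verified against the emitted sequence
  feats <- feature_sequences(genome, ann)
  dec <- purrr::map2(feats$seq[pcg], feats$gene[pcg], decompose_gene)
  realized_start <- purrr::map_chr(dec, "start_codon")
  realized_stop <- purrr::map_chr(dec, "stop_status")
  want_stop <- ifelse(ann$stop_plan[pcg] %in% c("T", "TA"),
                      paste0("incomplete_", ann$stop_plan[pcg]),
                      paste0("complete_", ann$stop_plan[pcg]))
  if (!all(realized_start == ann$start_codon[pcg]) ||
      !all(realized_stop == want_stop)) {
    stop("internal error: realized start/stop codons diverge from the plan",
         call. = FALSE)
  }
  out_ann <- ann
  out_ann$stop_codon[pcg] <- ann$stop_plan[pcg]
  out_ann$stop_plan <- NULL

  region_counts <- dplyr::bind_rows(
    dplyr::mutate(count_chars(genome$sequence), region = "full_genome"),
    purrr::map_dfr(c(PCGs = "PCG", tRNAs = "tRNA", rRNAs = "rRNA",
                     control_region = "control"), function(cat) {
      count_chars(paste(feats$seq[feats$category == cat], collapse = ""))
    }, .id = "region")
  ) %>% dplyr::select("region", dplyr::everything())

  # codon tallies from the realized PCG sequences (triplet chunking is the
  # ground truth here; the analysis path is exercised in tests)
  tally <- function(include_stops) {
    codons <- unlist(purrr::map(dec, function(d) {
      cc <- d$codons
      if (!include_stops && cc[length(cc)] %in% c("TAA", "TAG")) cc <- cc[-length(cc)]
      cc
    }))
    lv <- sort(.all_codons())
    tibble(codon = lv, count = as.integer(table(factor(codons, levels = lv))))
  }

  # planted hits must be exactly what the scanners see
  if (length(cr_row) == 1L) {
    cr_seq <- feats$seq[cr_row]
    verify_hits(cr_seq, planted)
    realized_hits <- scan_cr_sequence(cr_seq, config$scan_config)
    if (!identical(dplyr::arrange(as_tibble(planted), .data$start),
                   dplyr::arrange(as_tibble(realized_hits), .data$start))) {
      stop("internal error: control-region scan diverges from planted elements",
           call. = FALSE)
    }
  }

  manifest <- list(
    genome_length = L,
    region_base_counts = region_counts,
    codon_counts = tally(include_stops = FALSE),
    codon_counts_all = tally(include_stops = TRUE),
    gene_starts_stops = tibble(gene = feats$gene[pcg],
                               start_codon = realized_start,
                               stop_status = realized_stop),
    cr_hits = planted,
    gene_order = extract_gene_order(out_ann)
  )
  structure(
    list(genome = genome, annotation = out_ann, manifest = manifest,
         config = config),
    class = "mito_sim"
  )
}

#' @export
print.mito_sim <- function(x, ...) {
  cat(sprintf("<mito_sim> %s: %d bp, %d features, %d planted CR element(s)\n",
              x$genome$id, x$genome$length, nrow(x$annotation),
              nrow(x$manifest$cr_hits)))
  invisible(x)
}

#' Write the artifacts of a simulated mitogenome
#'
#' Emits `genome.fasta`, `features.tsv` and `manifest.json` into a
#' directory.
#'
#' @param sim A `mito_sim` object from [generate_mitogenome()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_sim <- function(sim, dir) {
  stopifnot(inherits(sim, "mito_sim"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_genome_fasta(sim$genome, file.path(dir, "genome.fasta"))
  write_feature_table(sim$annotation, file.path(dir, "features.tsv"))
  jsonlite::write_json(sim$manifest, file.path(dir, "manifest.json"),
                       dataframe = "columns", digits = NA, pretty = TRUE)
  invisible(dir)
}
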