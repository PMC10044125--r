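# The generator is exercised mostly through the perspectalis-like profile;
# one simulation per seed is shared across assertions to keep runtime down.

sim_cache <- new.env()
get_sim <- function(seed = 1) {
  key <- paste0("s", seed)
  if (is.null(sim_cache[[key]])) {
    sim_cache[[key]] <- generate_mitogenome(perspectalis_profile(), seed = seed)
  }
  sim_cache[[key]]
}

test_that("the perspectalis-like profile mirrors the published layout", {
  cfg <- perspectalis_profile()
  expect_s3_class(cfg, "mito_sim_config")
  expect_equal(nrow(cfg$features), 38L)
  cr <- cfg$features[cfg$features$category == "control", ]
  expect_equal(feature_length(cr$start, cr$end), 288L)
  ig <- intergenic_lengths(cfg$features, max(cfg$features$end))
  expect_equal(ig$spacer[ig$gene == "atp8"], -7L)
  expect_equal(nrow(cfg$cr_elements), 4L)
})

test_that("generation is deterministic for a fixed seed", {
  a <- get_sim(1)
  b <- generate_mitogenome(perspectalis_profile(), seed = 1)
  expect_identical(a$genome$sequence, b$genome$sequence)
  expect_equal(a$manifest$codon_counts, b$manifest$codon_counts)
  c_ <- generate_mitogenome(perspectalis_profile(), seed = 2)
  expect_false(identical(a$genome$sequence, c_$genome$sequence))
})

test_that("the emitted genome realizes the configured layout exactly", {
  sim <- get_sim(1)
  expect_equal(sim$genome$length, 15180L)
  expect_true(is_complete_annotation(sim$annotation))
  # planned starts and stops survive the annotated overlaps
  cu <- codon_usage(sim$genome, sim$annotation)
  expect_equal(cu$genes$start_codon[cu$genes$gene == "cox1"], "CGA")
  expect_equal(sort(unique(cu$genes$start_class)), c("ATN", "CGA"))
  expect_equal(cu$genes$stop_status[cu$genes$gene == "cox2"], "incomplete_T")
  expect_true(all(cu$genes$stop_status %in%
                    c("complete_TAA", "complete_TAG", "incomplete_T",
                      "incomplete_TA")))
})

test_that("control-region composition stays near its sampling target", {
  sim <- get_sim(1)
  ct <- composition_table(sim$genome, sim$annotation)
  cr_at <- ct$at_pct[ct$region == "control_region"]
  expect_lt(abs(cr_at - 96.2), 2)
})

test_that("the full pipeline recovers the manifest", {
  sim <- get_sim(1)
  # composition: exact base counts per region
  ct <- composition_table(sim$genome, sim$annotation)
  truth <- sim$manifest$region_base_counts
  expect_equal(ct$size, truth$total[match(ct$region, truth$region)])
  # codon usage: exact codon counts through decompose + count
  cu <- codon_usage(sim$genome, sim$annotation)
  expect_equal(cu$counts, sim$manifest$codon_counts)
  expect_equal(count_codons(cu$decompositions, include_stops = TRUE),
               sim$manifest$codon_counts_all)
  # gene order: template recovered, still one trnM translocation
  ord <- extract_gene_order(sim$annotation)
  expect_equal(ord, sim$manifest$gene_order)
  expect_equal(
    compare_orders(ord, ancestral_insect_order())$moved_genes, "trnM")
  # control region: planted hits recovered exactly
  hits <- control_region_report(sim$genome, sim$annotation)
  expect_equal(as.data.frame(hits), as.data.frame(sim$manifest$cr_hits),
               ignore_attr = TRUE)
})

test_that("infeasible configurations fail with the violated constraint named", {
  cfg <- perspectalis_profile()
  bad <- cfg
  bad$cr_elements$copies[bad$cr_elements$unit == "AT"] <- 200L
  expect_error(generate_mitogenome(bad, seed = 1), "control region")
  bad2 <- cfg
  bad2$features$stop_plan[bad2$features$gene == "nad2"] <- "T"
  expect_error(generate_mitogenome(bad2, seed = 1), "infeasible")
})

test_that("simulation artifacts round-trip through files", {
  sim <- get_sim(1)
  dir <- withr::local_tempdir()
  write_sim(sim, dir)
  expect_true(all(file.exists(file.path(
    dir, c("genome.fasta", "features.tsv", "manifest.json")))))
  g <- read_genome_fasta(file.path(dir, "genome.fasta"))
  expect_equal(g$sequence, sim$genome$sequence)
  ann <- read_feature_table(file.path(dir, "features.tsv"))
  expect_equal(ann$gene, sim$annotation$gene)
  expect_equal(ann$start, sim$annotation$start)
})

test_that("tidiers summarize simulations", {
  sim <- get_sim(1)
  td <- tidy(sim)
  expect_equal(nrow(td), 38L)
  expect_true("size" %in% names(td))
  gl <- glance(sim)
  expect_equal(gl$genome_length, 15180L)
  expect_equal(gl$n_pcg, 13L)
  expect_equal(gl$n_trna, 22L)
})
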