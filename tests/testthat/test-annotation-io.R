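test_that("feature tables in the published Location dialect parse correctly", {
  txt <- c(
    "Gene\tStrand\tLocation\tSize\tAnticodon",
    "trnM\tF\t1–68\t68\tCAT",
    "16S\tR\t12,681–14,050\t1370\t–",
    "trnN\tF\t6,076-6,141\t66\tGUU"
  )
  ann <- read_feature_table(txt)
  expect_equal(ann$gene, c("trnM", "rrnL", "trnN"))
  expect_equal(ann$category, c("tRNA", "rRNA", "tRNA"))
  expect_equal(ann$start, c(1L, 12681L, 6076L))
  expect_equal(ann$end, c(68L, 14050L, 6141L))
  # anticodons land in the DNA alphabet whatever the table printed
  expect_equal(ann$anticodon, c("CAT", NA, "GTT"))
})

test_that("parse errors name the offending row", {
  expect_error(
    read_feature_table(c("Gene\tStrand\tLocation", "x\tF\t12..80")),
    "malformed coordinate.*row 1"
  )
  expect_error(
    read_feature_table(c("Gene\tStrand\tStart\tEnd", "x\tZ\t1\t5")),
    "unknown strand symbol 'Z'"
  )
  expect_error(
    read_feature_table(c("Gene\tStrand\tStart\tEnd",
                         "x\tF\t1\t5", "x\tF\t6\t9")),
    "duplicate gene name"
  )
})

test_that("declared sizes are checked, not silently trusted", {
  txt <- c("Gene\tStrand\tStart\tEnd\tSize", "x\tF\t1\t10\t9")
  expect_warning(read_feature_table(txt), "declared 9, computed 10")
})

test_that("write/parse round-trips annotations exactly", {
  expect_equal(write_feature_table(toy_annotation()[0, ]),
               write_feature_table(toy_annotation())[1]) # header-only output
  withr::with_seed(11, {
    for (rep in 1:5) {
      n <- sample(3:12, 1)
      starts <- sort(sample.int(5000, n))
      ann <- tibble::tibble(
        gene = paste0("g", seq_len(n)),
        category = "PCG",
        strand = sample(c("F", "R"), n, TRUE),
        start = starts,
        end = starts + sample.int(300, n),
        anticodon = NA_character_,
        start_codon = sample(c(NA, "ATG", "ATT"), n, TRUE),
        stop_codon = sample(c(NA, "TAA", "T"), n, TRUE)
      )
      expect_equal(read_feature_table(write_feature_table(ann)), ann)
    }
  })
})

test_that("the shipped box tree moth annotation reproduces the published summary", {
  ann <- cydalima_annotation()
  expect_equal(nrow(ann), 38L)
  expect_true(is_complete_annotation(ann))
  expect_equal(max(ann$end), 15180L)
  census <- strand_census(ann)
  expect_equal(census$n[census$strand == "F"], 23L)
  expect_equal(census$n[census$strand == "R"], 14L)
  # every printed intergenic value matches the computed spacer, including
  # the trnQ row (43) and the circular closure after the control region (0)
  raw <- readr::read_tsv(
    system.file("extdata", "cydalima_perspectalis_features.tsv",
                package = "mitochar"),
    col_types = readr::cols(.default = "c"), progress = FALSE
  )
  printed <- as.integer(chartr("−", "-", raw$Intergenic))
  ig <- intergenic_lengths(ann, 15180L)
  expect_equal(ig$spacer, printed)
  expect_equal(ig$spacer[ig$gene == "trnI"], -3L)
  expect_equal(ig$spacer[ig$gene == "trnL1"], -44L)
})

test_that("feature lengths follow circular coordinate arithmetic", {
  expect_equal(feature_length(1, 68), 68L)
  expect_equal(feature_length(12681, 14050), 1370L)
  expect_equal(feature_length(5, 5), 1L)
  expect_equal(feature_length(5, 2, genome_length = 6), 4L)
  expect_error(feature_length(5, 2), "wrap")
  expect_error(feature_length(1, 20, genome_length = 10), "exceed")
  sizes <- feature_lengths(cydalima_annotation(), 15180L)$size
  expect_equal(sum(sizes[cydalima_annotation()$category == "tRNA"]), 1473L)
})

test_that("lengths plus spacers tile the circle exactly", {
  # holds with overlaps too, since overlaps enter as negative spacers
  withr::with_seed(21, {
    for (rep in 1:10) {
      L <- sample(200:1000, 1)
      n <- sample(3:10, 1)
      starts <- sort(sample.int(L - 20, n))
      ann <- tibble::tibble(
        gene = paste0("g", seq_len(n)), category = "PCG", strand = "F",
        start = starts,
        end = pmin(starts + sample.int(40, n), L)
      )
      ann <- ann[!duplicated(ann$start), ]
      lens <- feature_length(ann$start, ann$end, L)
      spacers <- intergenic_lengths(ann, L)$spacer
      expect_equal(sum(lens) + sum(spacers), L)
    }
  })
})

test_that("abutting genes have zero spacer and unsorted input errors", {
  ann <- tibble::tibble(gene = c("a", "b"), category = "PCG", strand = "F",
                        start = c(1L, 4L), end = c(3L, 6L))
  expect_equal(intergenic_lengths(ann, 6L)$spacer[1], 0L)
  expect_error(intergenic_lengths(ann[2:1, ], 6L), "sort")
})

test_that("strand census counts gene features only, matching a direct tally", {
  ann <- toy_annotation()
  cen <- strand_census(ann)
  expect_equal(sum(cen$n), 3L) # control region excluded
  withr::with_seed(31, {
    n <- 15
    ann <- tibble::tibble(
      gene = paste0("g", 1:n), category = "tRNA",
      strand = sample(c("F", "R"), n, TRUE),
      start = seq(1, by = 10, length.out = n),
      end = seq(5, by = 10, length.out = n),
      anticodon = "CAT"
    )
    cen <- strand_census(ann)
    expect_equal(cen$n[cen$strand == "F"], sum(ann$strand == "F"))
    expect_equal(cen$n[cen$strand == "R"], sum(ann$strand == "R"))
  })
  all_f <- tibble::tibble(gene = c("a", "b"), category = "PCG", strand = "F",
                          start = c(1L, 10L), end = c(6L, 15L))
  expect_equal(strand_census(all_f)$n, c(2L, 0L))
})

test_that("feature sequences are strand-corrected and wrap the origin", {
  g <- mito_genome("ATGC")
  expect_equal(extract_feature_sequence(g, 1, 4, "F"), "ATGC")
  expect_equal(extract_feature_sequence(g, 1, 4, "R"), "GCAT")
  expect_equal(extract_feature_sequence(mito_genome("AAACCC"), 5, 2), "CCAA")
  lin <- mito_genome("AAACCC", circular = FALSE)
  expect_error(extract_feature_sequence(lin, 5, 2), "not circular")
  # F and R extraction of the same range are reverse complements
  withr::with_seed(41, {
    g <- mito_genome(random_dna(200))
    for (rep in 1:10) {
      s <- sample.int(200, 1); e <- sample.int(200, 1)
      f <- extract_feature_sequence(g, s, e, "F")
      r <- extract_feature_sequence(g, s, e, "R")
      expect_equal(nchar(f), feature_length(s, e, 200))
      expect_equal(r, as.character(
        Biostrings::reverseComplement(Biostrings::DNAString(f))))
    }
  })
})

test_that("FASTA round-trips through 70-column wrapping", {
  withr::with_seed(51, {
    g <- mito_genome(random_dna(433), id = "toy_genome")
    path <- withr::local_tempfile(fileext = ".fasta")
    write_genome_fasta(g, path)
    expect_equal(read_genome_fasta(path)$sequence, g$sequence)
    expect_lte(max(nchar(readLines(path))), 70L)
  })
})
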