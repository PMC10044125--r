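test_that("the invertebrate mitochondrial code has the expected family structure", {
  code <- mito_genetic_code()
  expect_equal(nrow(code), 64L)
  expect_equal(sum(code$aa != "*"), 62L)
  expect_equal(sort(code$codon[code$aa == "*"]), c("TAA", "TAG"))
  expect_equal(code$aa[code$codon == "ATA"], "M")
  expect_equal(code$aa[code$codon == "TGA"], "W")
  expect_equal(code$aa[code$codon %in% c("AGA", "AGG")], c("S", "S"))
  fam <- table(code$family)
  expect_equal(as.integer(fam[c("Leu", "Ser", "Arg", "Met", "Trp", "Stop")]),
               c(6L, 8L, 4L, 2L, 2L, 2L))
  expect_true(all(startsWith(code$codon[code$family == "Arg"], "CG")))
})

test_that("gene decomposition handles complete and incomplete stops", {
  d <- decompose_gene("ATGAAATAA")
  expect_equal(d$codons, c("ATG", "AAA", "TAA"))
  expect_equal(d$start_codon, "ATG")
  expect_equal(d$stop_status, "complete_TAA")
  # a 682 bp gene (published cox2 length): 227 codons + trailing T
  withr::with_seed(91, {
    body <- paste(sample(c("A", "C", "G", "T"), 678, TRUE), collapse = "")
    d2 <- decompose_gene(paste0("ATG", body, "T"))
    expect_length(d2$codons, 227L)
    expect_equal(d2$trailing, "T")
    expect_equal(d2$stop_status, "incomplete_T")
  })
  expect_equal(decompose_gene("ATGAAATA")$stop_status, "incomplete_TA")
  expect_equal(decompose_gene("ATGAAA")$stop_status, "non_canonical")
  expect_equal(decompose_gene("ATGAAAGG")$stop_status, "non_canonical")
  expect_error(decompose_gene("AT"), "shorter")
})

test_that("decomposition length identity holds for arbitrary lengths", {
  withr::with_seed(101, {
    for (rep in 1:20) {
      n <- sample(3:500, 1)
      d <- decompose_gene(random_dna(n))
      expect_equal(3L * length(d$codons) + nchar(d$trailing), n)
      if (n %% 3 == 2) expect_equal(nchar(d$trailing), 2L)
    }
  })
})

test_that("start codons classify as ATN, CGA or other", {
  expect_equal(classify_start(c("ATT", "ATG", "ATA", "ATC")), rep("ATN", 4))
  expect_equal(classify_start("CGA"), "CGA")
  expect_equal(classify_start("GTG"), "other")
  expect_error(classify_start("AT"), "triplet")
})

test_that("terminal stop codons are excluded from counts, internal ones kept", {
  d <- decompose_gene("ATGAAATAA")
  counts <- count_codons(d, include_stops = FALSE)
  expect_equal(counts$count[counts$codon == "ATG"], 1L)
  expect_equal(counts$count[counts$codon == "TAA"], 0L)
  expect_equal(count_codons(d, include_stops = TRUE)$count[
    counts$codon == "TAA"], 1L)
  # internal TAA counted even when terminal excluded
  internal <- decompose_gene("ATGTAAAAATAA")
  expect_equal(count_codons(internal)$count[counts$codon == "TAA"], 1L)
  empty <- count_codons(list())
  expect_equal(sum(empty$count), 0L)
  expect_equal(nrow(empty), 64L)
})

test_that("codon tallies are additive over gene lists", {
  withr::with_seed(111, {
    genes <- lapply(1:6, function(i) decompose_gene(random_dna(3 * sample(5:60, 1))))
    whole <- count_codons(genes)
    parts <- lapply(genes, count_codons)
    summed <- Reduce(function(a, b) {
      a$count <- a$count + b$count; a
    }, parts)
    expect_equal(whole, summed)
  })
})

test_that("RSCU reproduces every published codon-table value at 2 dp", {
  cc <- cydalima_codon_counts()
  rs <- compute_rscu(cc)
  expect_equal(rs$rscu[rs$codon == "TTA"], 467 / mean(c(467, 17, 23, 2, 22, 0)))
  expect_equal(round_half_up(rs$rscu[rs$codon == "TTA"], 2), 5.28)
  expect_equal(round_half_up(rs$rscu[rs$codon == "AGA"], 2), 2.46)
  published <- cc$rscu_published[match(rs$codon, cc$codon)]
  expect_equal(round_half_up(rs$rscu, 2), published)
})

test_that("RSCU family means are 1 and scaling a family leaves RSCU unchanged", {
  code <- mito_genetic_code()
  withr::with_seed(121, {
    for (rep in 1:10) {
      counts <- tibble::tibble(codon = code$codon,
                               count = rpois(64, lambda = 20))
      rs <- compute_rscu(counts, code)
      means <- tapply(rs$rscu, rs$family, mean)
      totals <- tapply(rs$count, rs$family, sum)
      expect_equal(as.numeric(means[totals > 0]),
                   rep(1, sum(totals > 0)))
      # scale one family by an integer factor
      fam <- sample(unique(code$family), 1)
      scaled <- counts
      scaled$count[code$family == fam] <- 3L * scaled$count[code$family == fam]
      rs2 <- compute_rscu(scaled, code)
      expect_equal(rs2$rscu[code$family == fam], rs$rscu[code$family == fam])
    }
  })
  # a family never used is flagged, not divided by zero
  none <- tibble::tibble(codon = code$codon, count = 0L)
  none$count[none$codon == "TTT"] <- 5L
  rs0 <- compute_rscu(none, code)
  expect_true("Gly" %in% attr(rs0, "flagged_families"))
  expect_equal(rs0$rscu[rs0$family == "Gly"], rep(0, 4))
  # uniform counts within a family give RSCU 1 for every member
  uni <- tibble::tibble(codon = code$codon, count = 7L)
  expect_equal(compute_rscu(uni, code)$rscu, rep(1, 64))
})

test_that("amino-acid class totals and sense-codon total match the published table", {
  cc <- cydalima_codon_counts()
  totals <- amino_acid_totals(cc)
  get <- function(cls) totals$count[totals$aa_class == cls]
  expect_equal(get("Leu(UUR)"), 484L)
  expect_equal(get("Ile"), 469L)
  expect_equal(get("Phe"), 374L)
  expect_equal(total_sense_codons(cc), 3723L)
  zero <- tibble::tibble(codon = mito_genetic_code()$codon, count = 0L)
  expect_equal(sum(amino_acid_totals(zero)$count), 0L)
  expect_equal(total_sense_codons(zero), 0L)
  # brute-force: sense total equals the sum excluding TAA/TAG
  withr::with_seed(131, {
    counts <- tibble::tibble(codon = mito_genetic_code()$codon,
                             count = rpois(64, 9))
    expect_equal(total_sense_codons(counts),
                 sum(counts$count[!counts$codon %in% c("TAA", "TAG")]))
  })
})
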