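test_that("motif scanning finds exact and wildcard occurrences", {
  hit <- find_motif("CCATAGGTT", "ATAGG")
  expect_equal(nrow(hit), 1L)
  expect_equal(c(hit$start, hit$end), c(3L, 7L))
  expect_equal(nrow(find_motif("CCCCC", "ATAGG")), 0L)
  expect_equal(nrow(find_motif("ACG", "ACGTT")), 0L) # motif longer than seq
  # N wildcard and overlapping occurrences
  expect_equal(find_motif("AAAA", "AN")$start, 1:3)
})

test_that("motif hits equal a brute-force position scan on random sequences", {
  withr::with_seed(151, {
    for (rep in 1:15) {
      s <- random_dna(500, c(A = 0.4, C = 0.1, G = 0.1, T = 0.4))
      motif <- random_dna(sample(3:6, 1), c(A = 0.4, C = 0.1, G = 0.1, T = 0.4))
      expect_equal(find_motif(s, motif)$start, oracle_motif_scan(s, motif))
    }
  })
})

test_that("homopolymer runs are maximal with exact lengths", {
  expect_equal(nrow(find_homopolymer_runs("TTT", "T", min_len = 5)), 0L)
  h <- find_homopolymer_runs(paste0("AA", strrep("T", 17), "AA"), "T", 10)
  expect_equal(h$copies, 17L)
  expect_equal(c(h$start, h$end), c(3L, 19L))
  withr::with_seed(161, {
    for (rep in 1:15) {
      s <- random_at_rich(400)
      got <- find_homopolymer_runs(s, "T", 4)
      want <- oracle_runs(s, "T", 4)
      expect_equal(got$start, want$start)
      expect_equal(got$copies, want$len)
    }
  })
})

test_that("microsatellite arrays are maximal, with partial units in end only", {
  h <- find_microsatellites("ATATAT", "AT", min_copies = 3)
  expect_equal(h$copies, 3L)
  expect_equal(h$end, 6L)
  # trailing partial unit extends end but not copies
  h2 <- find_microsatellites("GGATATATA", "AT", min_copies = 3)
  expect_equal(h2$start, 3L)
  expect_equal(h2$copies, 3L)
  expect_equal(h2$end, 9L)
  withr::with_seed(171, {
    for (rep in 1:15) {
      s <- random_at_rich(300)
      got <- find_microsatellites(s, "AT", 3)
      want <- oracle_microsat(s, "AT", 3)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$copies, want$copies)
    }
  })
})

test_that("tandem repeats report maximal arrays at their smallest period", {
  h <- find_tandem_repeats("ACGACGACG", min_unit = 3, min_copies = 2)
  expect_equal(h$unit, "ACG")
  expect_equal(h$copies, 3L)
  # a planted 2 x 10 bp array
  arr <- strrep("ATAGGATTTT", 2)
  h2 <- find_tandem_repeats(paste0("CC", arr, "CC"), min_unit = 5, min_copies = 2)
  expect_equal(nchar(h2$unit), 10L)
  expect_equal(h2$start, 3L)
  # a dinucleotide array is not re-reported at larger periods
  expect_equal(nrow(find_tandem_repeats(strrep("AT", 14), 5, 2)), 0L)
  withr::with_seed(181, {
    for (rep in 1:10) {
      s <- random_at_rich(150)
      got <- find_tandem_repeats(s, 5, 2)
      want <- oracle_tandem(s, 5, 2)
      expect_equal(got$start, want$start)
      expect_equal(got$end, want$end)
      expect_equal(got$unit, want$unit)
    }
  })
})

test_that("AT microsatellites are contained in permissive tandem-repeat output", {
  withr::with_seed(191, {
    for (rep in 1:10) {
      s <- random_at_rich(300)
      micro <- find_microsatellites(s, "AT", 3)
      tand <- find_tandem_repeats(s, min_unit = 2, min_copies = 3)
      for (i in seq_len(nrow(micro))) {
        covered <- any(tand$start <= micro$start[i] & tand$end >= micro$end[i])
        expect_true(covered)
      }
    }
  })
})

test_that("every reported hit re-extracts to its literal description", {
  withr::with_seed(201, {
    for (rep in 1:10) {
      s <- random_at_rich(400)
      hits <- rbind(
        find_motif(s, "ATAGG"),
        find_homopolymer_runs(s, "T", 5),
        find_homopolymer_runs(s, "A", 5),
        find_microsatellites(s, "AT", 3),
        find_tandem_repeats(s, 4, 2)
      )
      expect_true(verify_hits(s, hits))
    }
  })
  bad <- tibble::tibble(kind = "homopolymer", start = 1L, end = 5L,
                        unit = "T", copies = 5L)
  expect_error(verify_hits("TATAT", bad), "inconsistent")
})

test_that("the control-region report finds exactly the planted elements", {
  sim <- generate_mitogenome(perspectalis_profile(), seed = 3)
  hits <- control_region_report(sim$genome, sim$annotation)
  expect_equal(nrow(hits), 4L)
  expect_setequal(hits$kind,
                  c("motif", "homopolymer", "microsatellite", "homopolymer"))
  expect_equal(hits$unit[hits$kind == "motif"], "ATAGGA")
  expect_equal(hits$copies[hits$unit == "T"], 17L)
  expect_equal(hits$copies[hits$unit == "AT"], 14L)
  expect_equal(hits$copies[hits$unit == "A"], 10L)
  expect_equal(as.data.frame(hits), as.data.frame(sim$manifest$cr_hits),
               ignore_attr = TRUE)
})

test_that("missing or empty control regions are errors", {
  g <- mito_genome("ATGCATGCAT")
  no_cr <- tibble::tibble(gene = "g1", category = "PCG", strand = "F",
                          start = 1L, end = 10L)
  expect_error(control_region_report(g, no_cr), "no control-region")
})
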