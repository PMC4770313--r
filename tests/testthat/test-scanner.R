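mir367 <- mature_mirna("hsa-miR-367-5p", "ACUGUUGCUAAUAUGCAACUCU")

test_that("seed windows are extracted at the documented miRNA positions", {
  w <- seed_window(mir367, "MIR3P", "6mer")
  expect_identical(w$start, 14L)
  expect_identical(w$end, 19L)
  expect_identical(w$seq, "UGCAAC")

  w5 <- seed_window(mir367, "MIR5P", "6mer")
  expect_identical(c(w5$start, w5$end), c(2L, 7L))
  expect_identical(w5$seq, "CUGUUG")

  expect_identical(seed_window(mir367, "MIR3P", "7merM8")$seq, "AUGCAAC")
  # alternative 3'-end anchor
  expect_identical(seed_window(mir367, "MIR3P", "6mer", anchor = 13)$seq,
                   "AUGCAA")

  m16 <- mature_mirna("m16", strrep("ACGU", 4))
  expect_error(seed_window(m16, "MIR3P", "7merM8"), "needs position 19")
})

test_that("target motifs are reverse complements with the A1 adenosine", {
  expect_identical(seed_motif("CUGUUG"), "CAACAG")
  expect_identical(seed_motif("UGCAAC"), "GUUGCA")
  # 5'-end A1: appended on the target's 3' side (across miRNA position 1)
  expect_identical(seed_motif("CUGUUG", TRUE, "target3"), "CAACAGA")
  # 3'-end A1: prepended (across the position flanking the 3' seed)
  expect_identical(seed_motif("UGCAAC", TRUE, "target5"), "AGUUGCA")
})

test_that("motif search reports all occurrences including overlaps", {
  expect_identical(find_motif_sites("AAAAGUUGCAAAAA", "GUUGCA"), 5L)
  expect_identical(find_motif_sites("AAAA", "GUUGCA"), integer(0))
  expect_identical(find_motif_sites("GUGUGUG", "GUG"), c(1L, 3L, 5L))
  expect_identical(find_motif_sites("", "GUG"), integer(0))
})

test_that("precedence assigns each locus exactly one seed kind", {
  # 5'-end: CAACAGA present, so the contained 6-mer is suppressed
  ts <- type_sites("UUCAACAGAUU", mir367, "MIR5P")
  expect_identical(nrow(ts), 1L)
  expect_identical(ts$kind, "7merA1")
  expect_identical(c(ts$start, ts$end), c(3L, 9L))

  # 3'-end bare 6-mer: flanks block both the A1 and the m13 extension
  ts2 <- type_sites("UUUUGUUGCAGUUU", mir367, "MIR3P")
  expect_identical(nrow(ts2), 1L)
  expect_identical(ts2$kind, "6mer")
  expect_identical(c(ts2$start, ts2$end), c(5L, 10L))

  # adenosine-flanked GUUGCA is typed as the larger 7merA1, not a 6mer
  ts3 <- type_sites("AAAAGUUGCAAAAA", mir367, "MIR3P")
  expect_identical(ts3$kind, "7merA1")

  expect_identical(nrow(type_sites(strrep("A", 40), mir367, "MIR5P")), 0L)
})

test_that("central sites require an 11-mer covering miRNA positions 9-12", {
  target <- paste0("UUUU", reverse_complement(substr(mir367$seq, 4, 14)),
                   "GGGG")
  cs <- find_central_sites(target, mir367)
  expect_identical(nrow(cs), 1L)
  expect_identical(c(cs$start, cs$end), c(5L, 15L))

  expect_identical(nrow(find_central_sites(strrep("A", 50), mir367)), 0L)

  # a locus matching two different s offsets is reported once: positions
  # 4-15 are G, so the s=4 and s=5 windows give the identical 11-C motif
  mir_per <- mature_mirna("periodic", paste0("AAU", strrep("G", 12),
                                             "CAUCAAA"))
  target2 <- paste0("UUUU", strrep("C", 11), "UUUU")
  cs2 <- find_central_sites(target2, mir_per)
  expect_identical(nrow(cs2), 1L)
})

test_that("duplex alignment scores follow the configured scheme", {
  d <- duplex_align(reverse_complement(mir367$seq), mir367)
  expect_identical(d$score, 22 * 5)
  expect_identical(d$annotation, strrep("|", 22))
  expect_identical(d$mirna_align, mir367$seq)

  all_a <- mature_mirna("polyA", strrep("A", 22))
  expect_identical(duplex_align(strrep("A", 25), all_a)$score, 0)
  expect_identical(duplex_align("", mir367)$score, 0)
  expect_error(duplex_align(strrep("A", 26), mir367), "25 nt")
})

test_that("duplex scores agree with an independent affine local aligner", {
  # Biostrings pairwiseAlignment with the pair-score matrix and the
  # equivalent affine penalties is an independent implementation
  bs_score <- function(win, mirseq) {
    S <- matrix(-3, 4, 4, dimnames = list(c("A", "C", "G", "U"),
                                          c("A", "C", "G", "U")))
    S["A", "U"] <- S["U", "A"] <- S["G", "C"] <- S["C", "G"] <- 5
    S["G", "U"] <- S["U", "G"] <- 1
    rev1 <- function(s) paste(rev(strsplit(s, "")[[1]]), collapse = "")
    pa <- Biostrings::pairwiseAlignment(
      Biostrings::BString(mirseq), Biostrings::BString(rev1(win)),
      type = "local", substitutionMatrix = S,
      gapOpening = 6, gapExtension = 2)
    max(0, Biostrings::score(pa))
  }
  set.seed(99)
  for (i in 1:30) {
    mirseq <- paste(sample(c("A", "C", "G", "U"), 22, TRUE), collapse = "")
    win <- paste(sample(c("A", "C", "G", "U"), sample(5:25, 1), TRUE),
                 collapse = "")
    expect_equal(duplex_align(win, mature_mirna("m", mirseq))$score,
                 bs_score(win, mirseq))
  }
})

test_that("scan_pair composes typing, conservation and coordinates", {
  tx <- transcript_model("t1", utr3 = "UUUUGUUGCAGUUU")
  sc <- scan_pair(tx, mir367)
  expect_identical(sum(sc$counts), 1L)
  expect_identical(unname(sc$counts["3U3P6mer_noncons"]), 1L)
  expect_identical(sc$sites$start_tx, 5L)
  expect_identical(sc$sites$end_tx, 10L)

  # no complementarity anywhere: zero vector
  tx0 <- transcript_model("t0", utr5 = strrep("A", 30),
                          cds = strrep("A", 60), utr3 = strrep("A", 60))
  polyA <- mature_mirna("polyA", strrep("A", 22))
  expect_identical(sum(scan_pair(tx0, polyA)$counts), 0L)

  # same motif planted once per region: one count in each region row
  motif <- "UUUUGUUGCAGUUU"
  tx3 <- transcript_model("t3", utr5 = motif, cds = motif, utr3 = motif)
  sc3 <- scan_pair(tx3, mir367)
  expect_identical(unname(sc3$counts["5U3P6mer_noncons"]), 1L)
  expect_identical(unname(sc3$counts["ORF3P6mer_noncons"]), 1L)
  expect_identical(unname(sc3$counts["3U3P6mer_noncons"]), 1L)
  expect_identical(sum(sc3$counts), 3L)
  # transcript coordinates are region-local plus the region offset
  expect_identical(sc3$sites$start_tx,
                   sc3$sites$start_region +
                     c(0L, nchar(motif), 2L * nchar(motif)))
})

test_that("conserved blocks flip the conservation half of the type", {
  tx <- transcript_model("t1", utr3 = "UUUUGUUGCAGUUU")
  blocks <- data.frame(transcript_id = "t1", start = 2L, end = 12L)
  sc <- scan_pair(tx, mir367, blocks)
  expect_identical(unname(sc$counts["3U3P6mer_cons"]), 1L)
  expect_identical(unname(sc$counts["3U3P6mer_noncons"]), 0L)

  # partial overlap is not containment
  blocks2 <- data.frame(transcript_id = "t1", start = 7L, end = 14L)
  sc2 <- scan_pair(tx, mir367, blocks2)
  expect_identical(unname(sc2$counts["3U3P6mer_noncons"]), 1L)

  # blocks for other transcripts are ignored
  blocks3 <- data.frame(transcript_id = "other", start = 2L, end = 12L)
  sc3 <- scan_pair(tx, mir367, blocks3)
  expect_identical(unname(sc3$counts["3U3P6mer_noncons"]), 1L)
})

test_that("scan_pair equals the brute-force oracle on random pairs", {
  set.seed(1234)
  for (i in 1:150) {
    cs <- random_scan_case()
    scan <- scan_pair(cs$tx, cs$mir, cs$blocks, align = FALSE)
    oracle <- oracle_scan_pair(cs$tx, cs$mir$seq, cs$mir$id, cs$blocks)
    expect_scan_equal(scan, oracle)
  }
})

test_that("the alternative 3'-end anchor shifts the scanned seed", {
  # anchor 13: 6-mer seed is positions 13-18 = AUGCAA, motif UUGCAU
  tx <- transcript_model("t1", utr3 = "CCCCUUGCAUCCCC")
  sc14 <- scan_pair(tx, mir367, anchor = 14)
  sc13 <- scan_pair(tx, mir367, anchor = 13)
  expect_identical(sum(sc14$counts), 0L)
  expect_identical(unname(sc13$counts["3U3P6mer_noncons"]), 1L)
})
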