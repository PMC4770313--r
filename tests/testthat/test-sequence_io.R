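fasta_file <- function(lines) {
  f <- withr::local_tempfile(fileext = ".fa", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("FASTA records are normalized to uppercase RNA in file order", {
  f <- fasta_file(c(">m", "acgt"))
  expect_identical(read_fasta(f), c(m = "ACGU"))

  f2 <- fasta_file(c(">a desc ignored", "ACGU", ">b", "ug", "ca"))
  got <- read_fasta(f2)
  expect_identical(names(got), c("a", "b"))
  expect_identical(unname(got), c("ACGU", "UGCA"))
})

test_that("empty FASTA yields an empty record set", {
  f <- fasta_file(character(0))
  expect_length(read_fasta(f), 0L)
})

test_that("ambiguity codes and strict-RNA violations are rejected", {
  f <- fasta_file(c(">m", "ACGNU"))
  expect_error(read_fasta(f), "alphabet error.*'m'.*position 4")
  # strict rna mode refuses DNA T instead of converting it
  f2 <- fasta_file(c(">d", "ACGT"))
  expect_error(read_fasta(f2, alphabet = "rna"), "alphabet error")
  expect_identical(unname(read_fasta(f2, alphabet = "auto")), "ACGU")
})

test_that("malformed FASTA is reported with its location", {
  f <- fasta_file(c("ACGU", ">m", "ACGU"))
  expect_error(read_fasta(f), "line 1")
  expect_error(read_fasta(tempfile("nope")), "not found")
})

test_that("transcripts are sliced by the region TSV and validated", {
  fa <- fasta_file(c(">t1", "ACGUACGUACGU"))
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("transcript_id\tutr5_len\tcds_len\tutr3_len",
               "t1\t3\t6\t3"), tsv)
  tx <- load_transcripts(fa, tsv)[["t1"]]
  expect_identical(tx$utr5, "ACG")
  expect_identical(tx$cds, "UACGUA")
  expect_identical(tx$utr3, "CGU")
  expect_identical(transcript_seq(tx), "ACGUACGUACGU")

  writeLines(c("transcript_id\tutr5_len\tcds_len\tutr3_len",
               "t1\t0\t12\t0"), tsv)
  tx2 <- load_transcripts(fa, tsv)[["t1"]]
  expect_identical(tx2$utr5, "")
  expect_identical(nchar(tx2$cds), 12L)

  writeLines(c("transcript_id\tutr5_len\tcds_len\tutr3_len",
               "t1\t3\t6\t4"), tsv)
  expect_error(load_transcripts(fa, tsv), "t1.*sum to 13.*12 nt")

  writeLines(c("transcript_id\tutr5_len\tcds_len\tutr3_len",
               "missing\t3\t6\t3"), tsv)
  expect_error(load_transcripts(fa, tsv), "missing from FASTA")
})

test_that("transcript write/load round trip preserves sequences and bounds", {
  set.seed(11)
  txs <- lapply(1:4, function(i) {
    rnd <- function(n) paste(sample(c("A", "C", "G", "U"), n, TRUE),
                             collapse = "")
    transcript_model(paste0("tx", i), rnd(sample(0:30, 1)),
                     rnd(sample(10:60, 1)), rnd(sample(0:50, 1)))
  })
  fa <- withr::local_tempfile(fileext = ".fa")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  write_transcripts(txs, fa, tsv)
  back <- load_transcripts(fa, tsv)
  for (i in seq_along(txs)) {
    expect_identical(back[[txs[[i]]$id]]$utr5, txs[[i]]$utr5)
    expect_identical(back[[txs[[i]]$id]]$cds, txs[[i]]$cds)
    expect_identical(back[[txs[[i]]$id]]$utr3, txs[[i]]$utr3)
  }
})

test_that("reverse_complement matches hand-derived cases", {
  expect_identical(reverse_complement("UGCAAC"), "GUUGCA")
  expect_identical(reverse_complement(""), "")
  expect_identical(reverse_complement("A"), "U")
  expect_error(reverse_complement("ACGT"), "alphabet")
})

test_that("reverse_complement is a length-preserving involution", {
  set.seed(5)
  for (i in 1:50) {
    s <- paste(sample(c("A", "C", "G", "U"), sample(1:80, 1), TRUE),
               collapse = "")
    rc <- reverse_complement(s)
    expect_identical(nchar(rc), nchar(s))
    expect_identical(reverse_complement(rc), s)
  }
})

test_that("mature miRNAs enforce minimum length and positional indexing", {
  expect_error(mature_mirna("short", "ACGUACGUACGU"), ">= 16 nt")
  m <- mature_mirna("hsa-miR-367-5p", "ACUGUUGCUAAUAUGCAACUCU")
  expect_identical(m$length, 22L)
  expect_identical(substr(m$seq, 2, 7), "CUGUUG")
})

test_that("fold-change tables keep only repressed records by default", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("mirna_id\ttranscript_id\tlog2fc",
               "m1\tt1\t-0.5", "m1\tt2\t0.3", "m1\tt3\t-1.2"), f)
  tab <- read_foldchange(f)
  expect_identical(nrow(tab), 2L)
  expect_true(all(tab$log2fc < 0))
  expect_identical(nrow(read_foldchange(f, filter_negative = FALSE)), 3L)
})

test_that("off-length AGO clusters are accepted with a warning", {
  f <- fasta_file(c(">c1", strrep("A", 41), ">c2", strrep("A", 30)))
  expect_warning(got <- read_clusters(f), "not 41 nt")
  expect_length(got, 2L)
  f2 <- fasta_file(c(">c1", strrep("A", 41)))
  expect_silent(read_clusters(f2))
})
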