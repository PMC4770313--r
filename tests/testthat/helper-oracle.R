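# Independent brute-force oracle for the scanner. Deliberately shares no
# code with the package: complementation via a lookup table, motif matching
# by substring equality at every offset, precedence by explicit interval
# containment over raw match sets, conservation by a loop over blocks.

ORACLE_COMP <- c(A = "U", C = "G", G = "C", U = "A")

oracle_rc <- function(s) {
  if (!nzchar(s)) return("")
  paste(rev(ORACLE_COMP[strsplit(s, "", fixed = TRUE)[[1]]]), collapse = "")
}

# target motif for one (mode, kind); NULL if the miRNA is too short
oracle_motif <- function(mirna_seq, mode, kind, anchor = 14L) {
  n <- nchar(mirna_seq)
  sub <- function(a, b) if (n < b) NULL else substr(mirna_seq, a, b)
  if (mode == "MIR5P") {
    switch(kind,
      "6mer"   = { s <- sub(2L, 7L); if (is.null(s)) NULL else oracle_rc(s) },
      "7merA1" = { s <- sub(2L, 7L); if (is.null(s)) NULL else
                     paste0(oracle_rc(s), "A") },
      "7merM8" = { s <- sub(2L, 8L); if (is.null(s)) NULL else oracle_rc(s) },
      "8mer"   = { s <- sub(2L, 8L); if (is.null(s)) NULL else
                     paste0(oracle_rc(s), "A") })
  } else {
    a <- anchor
    switch(kind,
      "6mer"   = { s <- sub(a, a + 5L); if (is.null(s)) NULL else
                     oracle_rc(s) },
      "7merA1" = { s <- sub(a, a + 5L); if (is.null(s)) NULL else
                     paste0("A", oracle_rc(s)) },
      "7merM8" = { s <- sub(a - 1L, a + 5L); if (is.null(s)) NULL else
                     oracle_rc(s) },
      "8mer"   = { s <- sub(a - 1L, a + 5L); if (is.null(s)) NULL else
                     paste0("A", oracle_rc(s)) })
  }
}

# every offset where motif occurs (overlaps included), by direct comparison
oracle_matches <- function(region_seq, motif) {
  k <- nchar(motif)
  n <- nchar(region_seq)
  if (k == 0L || n < k) return(integer(0))
  starts <- seq_len(n - k + 1L)
  starts[substring(region_seq, starts, starts + k - 1L) == motif]
}

# precedence-typed seed sites of one mode: raw matches per kind, larger
# kinds assigned first, smaller candidates dropped when contained in an
# assigned larger site's interval
oracle_type_sites <- function(region_seq, mirna_seq, mode, anchor = 14L) {
  assigned <- data.frame(start = integer(0), end = integer(0),
                         kind = character(0), stringsAsFactors = FALSE)
  for (kind in c("8mer", "7merM8", "7merA1", "6mer")) {
    motif <- oracle_motif(mirna_seq, mode, kind, anchor)
    if (is.null(motif)) next
    for (p in oracle_matches(region_seq, motif)) {
      e <- p + nchar(motif) - 1L
      inside <- FALSE
      if (nrow(assigned)) {
        for (q in seq_len(nrow(assigned))) {
          if (assigned$start[q] <= p && e <= assigned$end[q]) {
            inside <- TRUE
            break
          }
        }
      }
      if (!inside)
        assigned <- rbind(assigned,
                          data.frame(start = p, end = e, kind = kind,
                                     stringsAsFactors = FALSE))
    }
  }
  assigned[order(assigned$start, assigned$end), , drop = FALSE]
}

oracle_central_sites <- function(region_seq, mirna_seq) {
  n <- nchar(mirna_seq)
  starts <- integer(0)
  s <- 2L
  while (s <= 9L && s + 10L <= n) {
    motif <- oracle_rc(substr(mirna_seq, s, s + 10L))
    starts <- c(starts, oracle_matches(region_seq, motif))
    s <- s + 1L
  }
  sort(unique(starts))
}

oracle_conserved <- function(start, end, blocks) {
  if (is.null(blocks) || nrow(blocks) == 0L) return(FALSE)
  for (q in seq_len(nrow(blocks))) {
    if (blocks$start[q] <= start && end <= blocks$end[q]) return(TRUE)
  }
  FALSE
}

# canonical 54-type order, frozen literally (independent of site_types())
ORACLE_LABELS <- c(
  "3U5P6mer_cons", "3U5P6mer_noncons", "3U5P7merA1_cons",
  "3U5P7merA1_noncons", "3U5P7merM8_cons", "3U5P7merM8_noncons",
  "3U5P8mer_cons", "3U5P8mer_noncons",
  "3U3P6mer_cons", "3U3P6mer_noncons", "3U3P7merA1_cons",
  "3U3P7merA1_noncons", "3U3P7merM8_cons", "3U3P7merM8_noncons",
  "3U3P8mer_cons", "3U3P8mer_noncons",
  "ORF5P6mer_cons", "ORF5P6mer_noncons", "ORF5P7merA1_cons",
  "ORF5P7merA1_noncons", "ORF5P7merM8_cons", "ORF5P7merM8_noncons",
  "ORF5P8mer_cons", "ORF5P8mer_noncons",
  "ORF3P6mer_cons", "ORF3P6mer_noncons", "ORF3P7merA1_cons",
  "ORF3P7merA1_noncons", "ORF3P7merM8_cons", "ORF3P7merM8_noncons",
  "ORF3P8mer_cons", "ORF3P8mer_noncons",
  "5U5P6mer_cons", "5U5P6mer_noncons", "5U5P7merA1_cons",
  "5U5P7merA1_noncons", "5U5P7merM8_cons", "5U5P7merM8_noncons",
  "5U5P8mer_cons", "5U5P8mer_noncons",
  "5U3P6mer_cons", "5U3P6mer_noncons", "5U3P7merA1_cons",
  "5U3P7merA1_noncons", "5U3P7merM8_cons", "5U3P7merM8_noncons",
  "5U3P8mer_cons", "5U3P8mer_noncons",
  "3UCentral11mer_cons", "3UCentral11mer_noncons",
  "ORFCentral11mer_cons", "ORFCentral11mer_noncons",
  "5UCentral11mer_cons", "5UCentral11mer_noncons")

oracle_label <- function(region, mode, kind, conserved) {
  reg <- c(UTR3 = "3U", ORF = "ORF", UTR5 = "5U")[[region]]
  md <- c(MIR5P = "5P", MIR3P = "3P", CENTRAL = "Central")[[mode]]
  paste0(reg, md, kind, if (conserved) "_cons" else "_noncons")
}

# full scan of one pair: sites table + 54-count vector in canonical order
oracle_scan_pair <- function(tx, mirna_seq, mirna_id, blocks = NULL,
                             anchor = 14L) {
  counts <- stats::setNames(integer(54), ORACLE_LABELS)
  offs <- c(UTR5 = 0L, ORF = nchar(tx$utr5),
            UTR3 = nchar(tx$utr5) + nchar(tx$cds))
  txb <- NULL
  if (!is.null(blocks) && nrow(blocks))
    txb <- blocks[blocks$transcript_id == tx$id, , drop = FALSE]
  rows <- list()
  for (region in c("UTR5", "ORF", "UTR3")) {
    rseq <- switch(region, UTR5 = tx$utr5, ORF = tx$cds, UTR3 = tx$utr3)
    if (!nzchar(rseq)) next
    hits <- data.frame(start = integer(0), end = integer(0),
                       kind = character(0), mode = character(0),
                       stringsAsFactors = FALSE)
    for (mode in c("MIR5P", "MIR3P")) {
      ts <- oracle_type_sites(rseq, mirna_seq, mode, anchor)
      if (nrow(ts)) hits <- rbind(hits, cbind(ts, mode = mode))
    }
    cen <- oracle_central_sites(rseq, mirna_seq)
    if (length(cen))
      hits <- rbind(hits, data.frame(start = cen, end = cen + 10L,
                                     kind = "11mer", mode = "CENTRAL",
                                     stringsAsFactors = FALSE))
    for (q in seq_len(nrow(hits))) {
      st <- hits$start[q] + offs[[region]]
      en <- hits$end[q] + offs[[region]]
      cons <- oracle_conserved(st, en, txb)
      lab <- oracle_label(region, hits$mode[q], hits$kind[q], cons)
      counts[lab] <- counts[lab] + 1L
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mirna_id, transcript_id = tx$id, region = region,
        start_region = hits$start[q], end_region = hits$end[q],
        start_tx = st, end_tx = en, site_type_label = lab,
        conserved = cons, stringsAsFactors = FALSE)
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else data.frame(
    mirna_id = character(0), transcript_id = character(0),
    region = character(0), start_region = integer(0),
    end_region = integer(0), start_tx = integer(0), end_tx = integer(0),
    site_type_label = character(0), conserved = logical(0),
    stringsAsFactors = FALSE)
  sites <- sites[order(sites$start_tx, sites$end_tx,
                       sites$site_type_label), , drop = FALSE]
  rownames(sites) <- NULL
  list(sites = sites, counts = counts)
}

# random scan cases for the equivalence sweep
random_scan_case <- function() {
  bases <- c("A", "C", "G", "U")
  mir <- mature_mirna("rnd-mir", paste(sample(bases, 22, TRUE), collapse = ""))
  lens <- c(sample(0:60, 1), sample(20:120, 1), sample(20:120, 1))
  tx <- transcript_model("rnd-tx",
                         utr5 = paste(sample(bases, lens[1], TRUE), collapse = ""),
                         cds  = paste(sample(bases, lens[2], TRUE), collapse = ""),
                         utr3 = paste(sample(bases, lens[3], TRUE), collapse = ""))
  total <- sum(lens)
  blocks <- NULL
  if (total >= 20 && stats::runif(1) < 0.7) {
    nb <- sample(1:3, 1)
    s <- sample.int(total - 10L, nb, replace = TRUE)
    e <- pmin(total, s + sample(7:25, nb, replace = TRUE))
    keep <- e - s + 1L >= 8L
    if (any(keep)) {
      s2 <- s[keep]; e2 <- e[keep]; o <- order(s2)
      s <- s2[o]; e <- e2[o]
      # merge overlapping/abutting so both scanners see canonical blocks
      ms <- s[1]; me <- e[1]; outs <- integer(0); oute <- integer(0)
      for (q in seq_along(s)[-1]) {
        if (s[q] <= me + 1L) me <- max(me, e[q])
        else { outs <- c(outs, ms); oute <- c(oute, me); ms <- s[q]; me <- e[q] }
      }
      outs <- c(outs, ms); oute <- c(oute, me)
      blocks <- data.frame(transcript_id = "rnd-tx", start = outs,
                           end = oute, stringsAsFactors = FALSE)
    }
  }
  list(tx = tx, mir = mir, blocks = blocks)
}

expect_scan_equal <- function(scan, oracle) {
  testthat::expect_identical(unname(scan$counts), unname(oracle$counts))
  got <- scan$sites[, c("region", "start_region", "end_region", "start_tx",
                        "end_tx", "site_type_label", "conserved")]
  want <- oracle$sites[, c("region", "start_region", "end_region",
                           "start_tx", "end_tx", "site_type_label",
                           "conserved")]
  testthat::expect_identical(got, want)
}
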