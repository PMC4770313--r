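# Site detection: seed-motif matching for miRNA 5'-end and 3'-end modes,
# central 11-mer detection, precedence typing, and the 25-nt-window duplex
# alignment attached to each reported site. Calling is by perfect
# Watson-Crick complementarity of the seed (or central) span only -- no G:U
# wobble and no gaps inside the match; the duplex alignment is reported for
# inspection and never gates a call.

#' Seed definitions for the 5'-end and 3'-end pairing modes
#'
#' The conventional 5'-end seed is miRNA positions 2-7 (6mer) or 2-8
#' (7merM8), optionally augmented by a literal target adenosine across from
#' miRNA position 1 (7merA1, 8mer). The non-conventional 3'-end seed mirrors
#' this at positions `anchor..anchor+5` (6mer; 14-19 by default) and
#' `anchor-1..anchor+5` (7merM8; 13-19), with the A1-style adenosine across
#' from the position flanking the seed toward the miRNA 3' terminus
#' (position 20 for the default anchor), which places it on the target's 5'
#' side.
#'
#' @param anchor first miRNA position of the 3'-end 6mer seed, 14 (default)
#'   or 13.
#' @return data.frame with one row per (mode, kind): columns `mode`, `kind`,
#'   `start`, `end` (1-based inclusive miRNA positions), `requires_A1`, and
#'   `a1_side` (`"target3"`: A appended to the target motif; `"target5"`:
#'   prepended).
#' @export
seed_specs <- function(anchor = 14L) {
  anchor <- as.integer(anchor)
  if (!anchor %in% c(13L, 14L))
    stop("three-prime anchor must be 13 or 14", call. = FALSE)
  data.frame(
    mode = rep(c("MIR5P", "MIR3P"), each = 4L),
    kind = rep(c("6mer", "7merA1", "7merM8", "8mer"), 2L),
    start = c(2L, 2L, 2L, 2L, anchor, anchor, anchor - 1L, anchor - 1L),
    end = c(7L, 7L, 8L, 8L, anchor + 5L, anchor + 5L, anchor + 5L, anchor + 5L),
    requires_A1 = rep(c(FALSE, TRUE, FALSE, TRUE), 2L),
    a1_side = rep(c("target3", "target5"), each = 4L),
    stringsAsFactors = FALSE)
}

#' Extract the miRNA subsequence for one seed spec
#'
#' @param mirna a [mature_mirna()] (or plain RNA string).
#' @param mode `"MIR5P"` or `"MIR3P"`.
#' @param kind `"6mer"`, `"7merA1"`, `"7merM8"` or `"8mer"`.
#' @param anchor see [seed_specs()].
#' @return List with `start`, `end` (1-based inclusive miRNA positions) and
#'   `seq`, the seed subsequence. Errors if the miRNA is too short for the
#'   spec's end position.
#' @export
seed_window <- function(mirna, mode, kind, anchor = 14L) {
  seq <- if (inherits(mirna, "mature_mirna")) mirna$seq else
    normalize_rna(mirna, "auto")
  sp <- seed_specs(anchor)
  row <- sp[sp$mode == mode & sp$kind == kind, ]
  if (nrow(row) != 1L) stop("unknown seed spec: ", mode, " ", kind,
                            call. = FALSE)
  if (nchar(seq) < row$end)
    stop(sprintf("miRNA is %d nt but %s %s needs position %d",
                 nchar(seq), mode, kind, row$end), call. = FALSE)
  list(start = row$start, end = row$end,
       seq = substr(seq, row$start, row$end))
}

#' Target-side motif recognized by a seed
#'
#' The target motif is the reverse complement of the seed subsequence. For
#' A1-style kinds a literal `A` is added: the target base across from the
#' seed-flanking miRNA position must be adenosine regardless of the miRNA
#' base there. For 5'-end seeds this A lies on the target's 3' side
#' (appended); for 3'-end seeds, across from miRNA position 20, it lies on
#' the target's 5' side (prepended).
#'
#' @param seed_seq seed subsequence, 5' to 3'.
#' @param requires_A1 add the literal A.
#' @param a1_side `"target3"` (append) or `"target5"` (prepend).
#' @return Target motif, 5' to 3'.
#' @export
seed_motif <- function(seed_seq, requires_A1 = FALSE, a1_side = "target3") {
  m <- reverse_complement(seed_seq)
  if (!requires_A1) return(m)
  switch(a1_side,
         target3 = paste0(m, "A"),
         target5 = paste0("A", m),
         stop("a1_side must be 'target3' or 'target5'", call. = FALSE))
}

#' All occurrences of an exact motif in a sequence
#'
#' Overlapping occurrences are included. Matching is literal (perfect
#' Watson-Crick complementarity was already encoded in the motif).
#'
#' @param seq subject RNA string.
#' @param motif query motif.
#' @return Integer vector of 1-based start positions (possibly empty).
#' @export
find_motif_sites <- function(seq, motif) {
  if (!nzchar(seq) || !nzchar(motif) || nchar(motif) > nchar(seq))
    return(integer(0))
  # lookahead so overlapping hits are all reported; motifs are pure ACGU
  hits <- gregexpr(paste0("(?=", motif, ")"), seq, perl = TRUE)[[1]]
  if (hits[1] == -1L) return(integer(0))
  as.integer(hits)
}

#' Detect and type seed sites of one pairing mode in one region
#'
#' Every matched locus is assigned exactly one seed kind by the precedence
#' 8mer > 7merM8 > 7merA1 > 6mer: a locus already counted as a larger kind
#' is excluded from every smaller kind whose span it contains. Kinds whose
#' seed positions exceed the miRNA length contribute nothing.
#'
#' @param region_seq RNA string of one transcript region.
#' @param mirna a [mature_mirna()] or RNA string.
#' @param mode `"MIR5P"` or `"MIR3P"`.
#' @param anchor see [seed_specs()].
#' @return data.frame with columns `start`, `end` (1-based inclusive
#'   region-local span of the full motif, A1 base included) and `kind`.
#' @export
type_sites <- function(region_seq, mirna, mode, anchor = 14L) {
  seq <- if (inherits(mirna, "mature_mirna")) mirna$seq else
    normalize_rna(mirna, "auto")
  sp <- seed_specs(anchor)
  sp <- sp[sp$mode == mode, ]
  out <- data.frame(start = integer(0), end = integer(0),
                    kind = character(0), stringsAsFactors = FALSE)
  for (kind in c("8mer", "7merM8", "7merA1", "6mer")) {
    row <- sp[sp$kind == kind, ]
    if (nchar(seq) < row$end) next
    motif <- seed_motif(substr(seq, row$start, row$end),
                        row$requires_A1, row$a1_side)
    starts <- find_motif_sites(region_seq, motif)
    if (!length(starts)) next
    ends <- starts + nchar(motif) - 1L
    if (nrow(out)) {
      contained <- vapply(seq_along(starts), function(i)
        any(out$start <= starts[i] & ends[i] <= out$end), logical(1))
      starts <- starts[!contained]
      ends <- ends[!contained]
    }
    if (length(starts))
      out <- rbind(out, data.frame(start = starts, end = ends, kind = kind,
                                   stringsAsFactors = FALSE))
  }
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Detect central 11-mer sites in one region
#'
#' A central site is a target locus perfectly Watson-Crick paired to 11
#' contiguous miRNA positions `s..s+10` whose span entirely covers miRNA
#' positions 9-12 (so `s` ranges over 2..9, limited by miRNA length). A
#' locus matched by several values of `s` is reported once.
#'
#' @inheritParams type_sites
#' @return data.frame with columns `start`, `end` (11-nt spans).
#' @export
find_central_sites <- function(region_seq, mirna) {
  seq <- if (inherits(mirna, "mature_mirna")) mirna$seq else
    normalize_rna(mirna, "auto")
  s_max <- min(9L, nchar(seq) - 10L)
  starts <- integer(0)
  if (s_max >= 2L) {
    for (s in 2L:s_max) {
      motif <- reverse_complement(substr(seq, s, s + 10L))
      starts <- c(starts, find_motif_sites(region_seq, motif))
    }
  }
  starts <- sort(unique(starts))
  data.frame(start = starts, end = starts + 10L)
}

#' Default duplex scoring scheme
#'
#' miRanda-like values used by the reporting aligner: Watson-Crick pair +5,
#' G:U wobble +1, mismatch -3; the first column of a gap costs -8 and each
#' further column -2. No score threshold is applied anywhere: the alignment
#' is descriptive only.
#'
#' @return Named list `match`, `gu`, `mismatch`, `gap_open`, `gap_extend`.
#' @export
duplex_scoring <- function() {
  list(match = 5, gu = 1, mismatch = -3, gap_open = -8, gap_extend = -2)
}

pair_score_matrix <- function(scoring) {
  m <- matrix(scoring$mismatch, 4, 4, dimnames = list(RNA_BASES, RNA_BASES))
  m["A", "U"] <- m["U", "A"] <- m["G", "C"] <- m["C", "G"] <- scoring$match
  m["G", "U"] <- m["U", "G"] <- scoring$gu
  m
}

#' Local duplex alignment of a target window against a miRNA
#'
#' A Smith-Waterman local alignment of the miRNA (5' to 3') against the
#' reversed target window, so that aligned columns are antiparallel base
#' pairs. Affine gaps; G:U wobble and gaps are allowed here (reporting only)
#' even though they are forbidden in the seed match that calls the site.
#'
#' @param target_window target substring, at most 25 nt.
#' @param mirna a [mature_mirna()] or RNA string.
#' @param scoring see [duplex_scoring()].
#' @return Object of class `duplex_alignment`: `target_align` (3' to 5'),
#'   `mirna_align` (5' to 3'), `annotation` (`|` Watson-Crick, `:` G:U,
#'   space otherwise), `score`, and the aligned spans `target_start/end`
#'   (1-based in the 5' to 3' window) and `mirna_start/end`.
#' @export
duplex_align <- function(target_window, mirna, scoring = duplex_scoring()) {
  mseq <- if (inherits(mirna, "mature_mirna")) mirna$seq else
    normalize_rna(mirna, "auto")
  target_window <- normalize_rna(target_window, "auto")
  if (nchar(target_window) > 25L)
    stop("target window longer than 25 nt", call. = FALSE)
  empty <- structure(list(target_window = target_window, mirna_seq = mseq,
                          target_align = "", mirna_align = "",
                          annotation = "", score = 0,
                          target_start = NA_integer_, target_end = NA_integer_,
                          mirna_start = NA_integer_, mirna_end = NA_integer_),
                     class = "duplex_alignment")
  if (!nzchar(target_window) || !nzchar(mseq)) return(empty)

  a <- strsplit(mseq, "", fixed = TRUE)[[1]]
  b <- rev(strsplit(target_window, "", fixed = TRUE)[[1]])  # 3' to 5'
  n <- length(a); m <- length(b)
  S <- pair_score_matrix(scoring)
  open <- scoring$gap_open; ext <- scoring$gap_extend
  NEG <- -1e9
  M <- matrix(0, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)  # gap in target (miRNA base unpaired)
  Y <- matrix(NEG, n + 1L, m + 1L)  # gap in miRNA (target base unpaired)
  for (i in seq_len(n)) {
    si <- S[a[i], ]
    for (j in seq_len(m)) {
      diag <- max(M[i, j], X[i, j], Y[i, j]) + si[b[j]]
      M[i + 1L, j + 1L] <- max(0, diag)
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] + open, X[i, j + 1L] + ext)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] + open, Y[i + 1L, j] + ext)
    }
  }
  best <- which(M == max(M), arr.ind = TRUE)[1L, ]
  score <- max(M)
  if (score <= 0) return(empty)

  # traceback from the best paired cell
  i <- best[1L] - 1L; j <- best[2L] - 1L
  am <- ab <- ann <- character(0)
  state <- "M"
  while (i > 0L || j > 0L) {
    if (state == "M") {
      if (M[i + 1L, j + 1L] == 0) break
      s <- S[a[i], b[j]]
      am <- c(a[i], am); ab <- c(b[j], ab)
      ann <- c(if (s == scoring$match) "|" else if (s == scoring$gu) ":"
               else " ", ann)
      prev <- M[i + 1L, j + 1L] - s
      state <- if (abs(prev - M[i, j]) < 1e-9 || prev == 0) "M"
               else if (abs(prev - X[i, j]) < 1e-9) "X" else "Y"
      i <- i - 1L; j <- j - 1L
      if (state == "M" && M[i + 1L, j + 1L] == 0) break
    } else if (state == "X") {
      am <- c(a[i], am); ab <- c("-", ab); ann <- c(" ", ann)
      state <- if (abs(X[i + 1L, j + 1L] - (M[i, j + 1L] + open)) < 1e-9) "M"
               else "X"
      i <- i - 1L
    } else {
      am <- c("-", am); ab <- c(b[j], ab); ann <- c(" ", ann)
      state <- if (abs(Y[i + 1L, j + 1L] - (M[i + 1L, j] + open)) < 1e-9) "M"
               else "Y"
      j <- j - 1L
    }
  }
  mirna_start <- i + 1L; mirna_end <- best[1L] - 1L
  # b indices are reversed window coordinates; convert to 5'->3' positions
  b_start <- j + 1L; b_end <- best[2L] - 1L
  structure(list(target_window = target_window, mirna_seq = mseq,
                 target_align = paste(ab, collapse = ""),
                 mirna_align = paste(am, collapse = ""),
                 annotation = paste(ann, collapse = ""),
                 score = score,
                 target_start = m - b_end + 1L, target_end = m - b_start + 1L,
                 mirna_start = mirna_start, mirna_end = mirna_end),
            class = "duplex_alignment")
}

#' @export
print.duplex_alignment <- function(x, ...) {
  cat(sprintf("<duplex_alignment> score %.1f\n", x$score))
  if (nzchar(x$target_align)) {
    cat(sprintf("  target 3'-%s-5' (window %d-%d)\n", x$target_align,
                x$target_end, x$target_start))
    cat(sprintf("            %s\n", x$annotation))
    cat(sprintf("  miRNA  5'-%s-3' (bases %d-%d)\n", x$mirna_align,
                x$mirna_start, x$mirna_end))
  }
  invisible(x)
}

# 25-nt window centered on a site span, clipped to the region
site_window <- function(region_seq, start, end) {
  center <- (start + end) %/% 2L
  ws <- max(1L, center - 12L)
  we <- min(nchar(region_seq), center + 12L)
  if (we - ws + 1L > 25L) we <- ws + 24L
  list(seq = substr(region_seq, ws, we), start = ws, end = we)
}

#' Scan one miRNA-transcript pair for all 54 site types
#'
#' Runs seed typing for both pairing modes plus central detection on each of
#' the three regions, annotates conservation by containment in the supplied
#' conserved blocks, attaches a 25-nt-window duplex alignment to each site,
#' and tallies the canonical 54-type count vector. Site calling is exact
#' seed/central complementarity; the alignment never changes a call.
#'
#' @param transcript a [transcript_model()].
#' @param mirna a [mature_mirna()].
#' @param blocks conserved blocks as returned by [load_conserved_blocks()]
#'   (already filtered to length >= 8 and merged), or `NULL` for none.
#' @param anchor 3'-end seed anchor, see [seed_specs()].
#' @param align attach duplex alignments (default `TRUE`; `FALSE` leaves the
#'   alignment columns `NA`, useful in large property sweeps).
#' @return Object of class `site_scan`: list with `sites` (data.frame in the
#'   documented column order) and `counts` (named integer vector of length
#'   54 in canonical type order).
#' @export
scan_pair <- function(transcript, mirna, blocks = NULL, anchor = 14L,
                      align = TRUE) {
  stopifnot(inherits(transcript, "transcript_model"),
            inherits(mirna, "mature_mirna"))
  tx_blocks <- NULL
  if (!is.null(blocks) && nrow(blocks)) {
    tx_blocks <- blocks[blocks$transcript_id == transcript$id, , drop = FALSE]
  }
  offsets <- region_offsets(transcript)
  counts <- empty_count_vector()
  rows <- list()
  for (region in c("UTR5", "ORF", "UTR3")) {
    rseq <- region_seq(transcript, region)
    if (!nzchar(rseq)) next
    found <- list()
    for (mode in c("MIR5P", "MIR3P")) {
      ts <- type_sites(rseq, mirna, mode, anchor)
      if (nrow(ts)) found[[mode]] <- cbind(ts, mode = mode)
    }
    cs <- find_central_sites(rseq, mirna)
    if (nrow(cs)) found[["CENTRAL"]] <- cbind(cs, kind = "11mer",
                                              mode = "CENTRAL")
    for (f in found) {
      for (k in seq_len(nrow(f))) {
        start <- f$start[k]; end <- f$end[k]
        start_tx <- start + offsets[[region]]
        end_tx <- end + offsets[[region]]
        conserved <- is_conserved(start_tx, end_tx, tx_blocks)
        idx <- site_type_index(region, f$mode[k], f$kind[k], conserved)
        counts[idx] <- counts[idx] + 1L
        if (align) {
          win <- site_window(rseq, start, end)
          dup <- duplex_align(win$seq, mirna)
          a_score <- dup$score
          a_t <- dup$target_align; a_m <- dup$mirna_align
        } else {
          a_score <- NA_real_; a_t <- NA_character_; a_m <- NA_character_
        }
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mirna$id, transcript_id = transcript$id,
          region = region, start_region = start, end_region = end,
          start_tx = start_tx, end_tx = end_tx,
          site_type_label = site_types_cached()$label[idx],
          conserved = conserved, align_score = a_score,
          duplex_target = a_t, duplex_mirna = a_m,
          stringsAsFactors = FALSE)
      }
    }
  }
  sites <- if (length(rows)) do.call(rbind, rows) else data.frame(
    mirna_id = character(0), transcript_id = character(0),
    region = character(0), start_region = integer(0), end_region = integer(0),
    start_tx = integer(0), end_tx = integer(0),
    site_type_label = character(0), conserved = logical(0),
    align_score = numeric(0), duplex_target = character(0),
    duplex_mirna = character(0), stringsAsFactors = FALSE)
  sites <- sites[order(sites$start_tx, sites$end_tx, sites$site_type_label), ,
                 drop = FALSE]
  rownames(sites) <- NULL
  structure(list(sites = sites, counts = counts,
                 mirna_id = mirna$id, transcript_id = transcript$id),
            class = "site_scan")
}

#' @export
print.site_scan <- function(x, ...) {
  cat(sprintf("<site_scan> %s vs %s: %d site(s), %d type(s) hit\n",
              x$mirna_id, x$transcript_id, nrow(x$sites),
              sum(x$counts > 0)))
  if (nrow(x$sites)) {
    print(x$sites[, c("region", "start_tx", "end_tx", "site_type_label",
                      "conserved", "align_score")])
  }
  invisible(x)
}

#' Write a site table as TSV
#' @param scan a `site_scan` (or its `sites` data.frame).
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_sites <- function(scan, path) {
  sites <- if (inherits(scan, "site_scan")) scan$sites else scan
  utils::write.table(sites, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
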