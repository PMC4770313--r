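#' @useDynLib mirsite, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

RNA_BASES <- c("A", "C", "G", "U")

#' Normalize a nucleotide string to the RNA alphabet
#'
#' Uppercases and, when `alphabet` is `"auto"`, converts DNA `T` to RNA `U`.
#' Any residual character outside `{A,C,G,U}` is an error: ambiguity codes
#' (N, R, Y, ...) are rejected because every downstream operation assumes an
#' unambiguous Watson-Crick pairing partner.
#'
#' @param seq character scalar, nucleotide sequence.
#' @param alphabet `"auto"` (accept DNA, convert T to U) or `"rna"` (strict).
#' @param id record identifier used in error messages.
#' @return The normalized RNA string.
#' @export
normalize_rna <- function(seq, alphabet = c("auto", "rna"), id = "<seq>") {
  alphabet <- match.arg(alphabet)
  stopifnot(is.character(seq), length(seq) == 1L)
  s <- toupper(seq)
  if (alphabet == "auto") s <- chartr("T", "U", s)
  if (nzchar(s)) {
    ch <- strsplit(s, "", fixed = TRUE)[[1]]
    bad <- which(!ch %in% RNA_BASES)
    if (length(bad)) {
      stop(sprintf("alphabet error in record '%s': character '%s' at position %d",
                   id, ch[bad[1]], bad[1]), call. = FALSE)
    }
  }
  s
}

#' Read a FASTA file of RNA (or DNA) sequences
#'
#' Records are returned in file order, uppercased, with T converted to U when
#' `alphabet = "auto"`. Sequences containing ambiguity codes are rejected.
#'
#' @param path FASTA file.
#' @param alphabet `"auto"` or `"rna"` (see [normalize_rna()]).
#' @return Named character vector of RNA sequences (names are record ids,
#'   truncated at the first whitespace).
#' @export
read_fasta <- function(path, alphabet = c("auto", "rna")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  first <- readLines(path, n = 1L)
  if (length(first) == 1L && nzchar(trimws(first)) && !startsWith(first, ">")) {
    stop(sprintf("malformed FASTA '%s': line 1 does not start with '>'", path),
         call. = FALSE)
  }
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) stop(sprintf("malformed FASTA '%s': %s",
                                                   path, conditionMessage(e)),
                                           call. = FALSE))
  if (length(set) == 0L) return(stats::setNames(character(0), character(0)))
  ids <- sub("\\s.*$", "", names(set))
  seqs <- as.character(set)
  out <- vapply(seq_along(seqs), function(i)
    normalize_rna(seqs[i], alphabet, id = ids[i]), character(1))
  stats::setNames(out, ids)
}

#' Construct a mature miRNA record
#'
#' A mature miRNA is held 5' to 3'; positional indexing used throughout the
#' package (seed positions 2-7, 3'-end positions 14-19, central 9-12) is
#' 1-based from the 5' end.
#'
#' @param id miRNA identifier (e.g. `"hsa-miR-367-5p"`).
#' @param seq sequence, RNA or DNA alphabet.
#' @return Object of class `mature_mirna` with fields `id`, `seq`, `length`.
#' @export
mature_mirna <- function(id, seq) {
  seq <- normalize_rna(seq, "auto", id = id)
  if (nchar(seq) < 16L)
    stop(sprintf("miRNA '%s' is %d nt; mature miRNAs must be >= 16 nt",
                 id, nchar(seq)), call. = FALSE)
  structure(list(id = id, seq = seq, length = nchar(seq)),
            class = "mature_mirna")
}

#' @export
print.mature_mirna <- function(x, ...) {
  cat(sprintf("<mature_mirna> %s (%d nt)\n  5'-%s-3'\n", x$id, x$length, x$seq))
  invisible(x)
}

#' Read mature miRNAs from FASTA
#'
#' @inheritParams read_fasta
#' @return List of [mature_mirna()] objects, in file order.
#' @export
read_mirnas <- function(path, alphabet = c("auto", "rna")) {
  seqs <- read_fasta(path, alphabet)
  mapply(mature_mirna, names(seqs), seqs, SIMPLIFY = FALSE, USE.NAMES = TRUE)
}

#' Construct a transcript model partitioned into 5' UTR, CDS and 3' UTR
#'
#' The full transcript is the concatenation `utr5 + cds + utr3`; any region
#' may be empty. Coordinates reported by the scanner are 1-based inclusive,
#' both region-local and in full-transcript space.
#'
#' @param id transcript identifier (gene symbol or RefSeq accession).
#' @param utr5,cds,utr3 region sequences (RNA or DNA alphabet; may be `""`).
#' @return Object of class `transcript_model`.
#' @export
transcript_model <- function(id, utr5 = "", cds = "", utr3 = "") {
  structure(list(id = id,
                 utr5 = normalize_rna(utr5, "auto", id = paste0(id, ":utr5")),
                 cds  = normalize_rna(cds,  "auto", id = paste0(id, ":cds")),
                 utr3 = normalize_rna(utr3, "auto", id = paste0(id, ":utr3"))),
            class = "transcript_model")
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s: 5'UTR %d nt | CDS %d nt | 3'UTR %d nt\n",
              x$id, nchar(x$utr5), nchar(x$cds), nchar(x$utr3)))
  invisible(x)
}

#' Full transcript sequence of a transcript model
#' @param tx a `transcript_model`.
#' @return RNA string `utr5 + cds + utr3`.
#' @export
transcript_seq <- function(tx) paste0(tx$utr5, tx$cds, tx$utr3)

# 0-based offset of each region in full-transcript space
region_offsets <- function(tx) {
  c(UTR5 = 0L, ORF = nchar(tx$utr5), UTR3 = nchar(tx$utr5) + nchar(tx$cds))
}

region_seq <- function(tx, region) {
  switch(region, UTR5 = tx$utr5, ORF = tx$cds, UTR3 = tx$utr3,
         stop("unknown region: ", region))
}

#' Load transcripts from FASTA plus a region-boundary TSV
#'
#' The sidecar TSV must have header columns `transcript_id`, `utr5_len`,
#' `cds_len`, `utr3_len` (non-negative integers). For every row the three
#' lengths must sum to the FASTA sequence length; the transcript is then
#' built by slicing.
#'
#' @param fasta transcript FASTA file.
#' @param regions_tsv tab-separated region-length table.
#' @return Named list of [transcript_model()] objects in TSV row order.
#' @export
load_transcripts <- function(fasta, regions_tsv) {
  seqs <- read_fasta(fasta, "auto")
  if (!file.exists(regions_tsv))
    stop("file not found: ", regions_tsv, call. = FALSE)
  tab <- utils::read.delim(regions_tsv, stringsAsFactors = FALSE)
  need <- c("transcript_id", "utr5_len", "cds_len", "utr3_len")
  if (!all(need %in% names(tab)))
    stop("regions TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  out <- vector("list", nrow(tab))
  for (i in seq_len(nrow(tab))) {
    id <- tab$transcript_id[i]
    if (!id %in% names(seqs))
      stop(sprintf("transcript '%s' in regions TSV missing from FASTA", id),
           call. = FALSE)
    lens <- as.integer(tab[i, c("utr5_len", "cds_len", "utr3_len")])
    if (anyNA(lens) || any(lens < 0L))
      stop(sprintf("non-negative integer lengths required for '%s'", id),
           call. = FALSE)
    s <- seqs[[id]]
    if (sum(lens) != nchar(s))
      stop(sprintf(
        "region lengths for '%s' sum to %d but sequence is %d nt",
        id, sum(lens), nchar(s)), call. = FALSE)
    out[[i]] <- transcript_model(
      id,
      utr5 = substr(s, 1L, lens[1]),
      cds  = substr(s, lens[1] + 1L, lens[1] + lens[2]),
      utr3 = substr(s, lens[1] + lens[2] + 1L, sum(lens)))
  }
  stats::setNames(out, tab$transcript_id)
}

#' Write transcripts as FASTA plus region TSV
#'
#' Inverse of [load_transcripts()]: writing then reloading reproduces the
#' same sequences and region boundaries.
#'
#' @param transcripts list of `transcript_model`s.
#' @param fasta,regions_tsv output paths.
#' @return Invisibly, the two paths.
#' @export
write_transcripts <- function(transcripts, fasta, regions_tsv) {
  seqs <- vapply(transcripts, transcript_seq, character(1))
  ids <- vapply(transcripts, function(t) t$id, character(1))
  set <- Biostrings::BStringSet(stats::setNames(seqs, ids))
  Biostrings::writeXStringSet(set, fasta)
  tab <- data.frame(
    transcript_id = ids,
    utr5_len = vapply(transcripts, function(t) nchar(t$utr5), integer(1)),
    cds_len  = vapply(transcripts, function(t) nchar(t$cds),  integer(1)),
    utr3_len = vapply(transcripts, function(t) nchar(t$utr3), integer(1)))
  utils::write.table(tab, regions_tsv, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(c(fasta = fasta, regions_tsv = regions_tsv))
}

#' Antiparallel Watson-Crick reverse complement of an RNA string
#'
#' @param seq RNA string over `{A,C,G,U}`.
#' @return The reverse complement, an involution preserving length.
#' @export
reverse_complement <- function(seq) {
  seq <- normalize_rna(seq, "rna")
  if (!nzchar(seq)) return("")
  comp <- chartr("ACGU", "UGCA", seq)
  paste(rev(strsplit(comp, "", fixed = TRUE)[[1]]), collapse = "")
}

#' Read a protein fold-change table
#'
#' TSV with header `mirna_id`, `transcript_id`, `log2fc`. By default rows
#' with non-negative log2 fold change are dropped, keeping only repressed
#' targets: the regression is trained on repression, so the modelling
#' functions require `log2fc < 0`.
#'
#' @param path TSV file.
#' @param filter_negative drop rows with `log2fc >= 0` (default `TRUE`).
#' @return data.frame with columns `mirna_id`, `transcript_id`, `log2fc`.
#' @export
read_foldchange <- function(path, filter_negative = TRUE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("mirna_id", "transcript_id", "log2fc")
  if (!all(need %in% names(tab)))
    stop("fold-change TSV must have columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  tab$log2fc <- as.numeric(tab$log2fc)
  if (filter_negative) tab <- tab[!is.na(tab$log2fc) & tab$log2fc < 0, ]
  rownames(tab) <- NULL
  tab[need]
}

#' Read AGO-bound cluster sequences (PAR-CLIP style)
#'
#' Clusters are short mRNA fragments centred on crosslink sites; the source
#' protocol produces 41-nt clusters, so other lengths are accepted with a
#' warning.
#'
#' @param path FASTA file of cluster sequences.
#' @param expected_length nominal cluster length (default 41).
#' @return Named character vector of RNA sequences.
#' @export
read_clusters <- function(path, expected_length = 41L) {
  seqs <- read_fasta(path, "auto")
  off <- nchar(seqs) != expected_length
  if (any(off))
    warning(sprintf("%d of %d clusters are not %d nt (e.g. '%s')",
                    sum(off), length(seqs), expected_length,
                    names(seqs)[which(off)[1]]), call. = FALSE)
  seqs
}
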