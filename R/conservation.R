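# Conservation annotation. The package consumes precomputed conserved
# blocks (e.g. from a multiple-species alignment intersected across human,
# chimp, mouse, rat and dog and mapped into mRNA coordinates) as BED in
# transcript space; only blocks of 8 nt or more are considered. A site is
# conserved iff its full span (A1 base included) lies entirely within one
# merged block -- containment, not mere overlap.

#' Load conserved blocks from BED (transcript space)
#'
#' BED3, 0-based half-open, with the chrom column holding the transcript id.
#' Extra columns are ignored. Coordinates are converted to 1-based
#' inclusive; blocks shorter than `min_length` are dropped; the remainder
#' are sorted and merged per transcript (overlapping or abutting blocks
#' become one).
#'
#' @param path BED file.
#' @param min_length minimum block length kept (default 8 nt).
#' @return data.frame with columns `transcript_id`, `start`, `end`,
#'   `length` (1-based inclusive).
#' @export
load_conserved_blocks <- function(path, min_length = 8L) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  keep <- nzchar(trimws(lines))
  lines <- lines[keep]
  lineno <- which(keep)
  if (!length(lines))
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  fields <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(fields)) {
    f <- fields[[i]]
    if (length(f) < 3L)
      stop(sprintf("malformed BED line %d: fewer than 3 fields", lineno[i]),
           call. = FALSE)
    if (is.na(suppressWarnings(as.integer(f[2]))) ||
        is.na(suppressWarnings(as.integer(f[3]))))
      stop(sprintf("malformed BED line %d: non-integer coordinates",
                   lineno[i]), call. = FALSE)
  }
  tx <- vapply(fields, `[[`, character(1), 1)
  s0 <- as.integer(vapply(fields, `[[`, character(1), 2))
  e0 <- as.integer(vapply(fields, `[[`, character(1), 3))
  if (any(e0 < s0))
    stop(sprintf("malformed BED line %d: end before start",
                 lineno[which(e0 < s0)[1]]), call. = FALSE)
  # 0-based half-open -> 1-based inclusive
  df <- data.frame(transcript_id = tx, start = s0 + 1L, end = e0,
                   stringsAsFactors = FALSE)
  df <- df[df$end - df$start + 1L >= min_length, , drop = FALSE]
  if (!nrow(df))
    return(data.frame(transcript_id = character(0), start = integer(0),
                      end = integer(0), length = integer(0)))
  merged <- lapply(split(df, df$transcript_id), function(d) {
    r <- IRanges::reduce(IRanges::IRanges(d$start, d$end))
    data.frame(transcript_id = d$transcript_id[1],
               start = IRanges::start(r), end = IRanges::end(r),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, merged)
  out <- out[order(out$transcript_id, out$start), , drop = FALSE]
  out$length <- out$end - out$start + 1L
  rownames(out) <- NULL
  out
}

#' Is a site span conserved?
#'
#' True iff the span lies entirely within one conserved block (containment;
#' partial overlap does not qualify).
#'
#' @param start,end 1-based inclusive transcript coordinates of the site
#'   span (seed match plus A1 base where applicable).
#' @param blocks merged blocks for this transcript (data.frame with `start`,
#'   `end`), or `NULL`/empty for none.
#' @return Logical scalar.
#' @export
is_conserved <- function(start, end, blocks) {
  if (is.null(blocks) || nrow(blocks) == 0L) return(FALSE)
  any(blocks$start <= start & end <= blocks$end)
}
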