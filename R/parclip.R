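# Classification of AGO-bound cluster sequences (PAR-CLIP style) by the
# kinds of miRNA binding motifs they contain. "Conventional" means any
# miRNA 5'-end seed kind; 3'-end seed kinds and central 11-mers are
# non-conventional. Conservation is not evaluated at this stage (clusters
# need no transcript mapping to be classified).

#' Classify one AGO cluster against a miRNA library
#'
#' Scans the cluster with every miRNA for all 5'-end and 3'-end seed kinds
#' and central 11-mers, then derives the category from the union of hits:
#' `conventional_only`, `nonconventional_only`, `both`, or `none`.
#'
#' @param cluster_seq cluster sequence (RNA or DNA alphabet).
#' @param library list of [mature_mirna()] objects (non-empty).
#' @param cluster_id identifier carried into the output.
#' @param anchor 3'-end seed anchor (see [seed_specs()]).
#' @return Object of class `cluster_call`: `cluster_id`, `hits` (data.frame
#'   `mirna_id`, `mode`, `kind`, `start`, `end`), `category`.
#' @export
classify_cluster <- function(cluster_seq, library, cluster_id = "<cluster>",
                             anchor = 14L) {
  if (!length(library)) stop("empty miRNA library", call. = FALSE)
  seq <- normalize_rna(cluster_seq, "auto", id = cluster_id)
  rows <- list()
  for (mir in library) {
    for (mode in c("MIR5P", "MIR3P")) {
      ts <- type_sites(seq, mir, mode, anchor)
      if (nrow(ts))
        rows[[length(rows) + 1L]] <- data.frame(
          mirna_id = mir$id, mode = mode, kind = ts$kind,
          start = ts$start, end = ts$end, stringsAsFactors = FALSE)
    }
    cs <- find_central_sites(seq, mir)
    if (nrow(cs))
      rows[[length(rows) + 1L]] <- data.frame(
        mirna_id = mir$id, mode = "CENTRAL", kind = "11mer",
        start = cs$start, end = cs$end, stringsAsFactors = FALSE)
  }
  hits <- if (length(rows)) do.call(rbind, rows) else data.frame(
    mirna_id = character(0), mode = character(0), kind = character(0),
    start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  conv <- any(hits$mode == "MIR5P")
  nonconv <- any(hits$mode %in% c("MIR3P", "CENTRAL"))
  category <- if (conv && nonconv) "both"
              else if (conv) "conventional_only"
              else if (nonconv) "nonconventional_only"
              else "none"
  structure(list(cluster_id = cluster_id, hits = hits, category = category),
            class = "cluster_call")
}

#' @export
print.cluster_call <- function(x, ...) {
  cat(sprintf("<cluster_call> %s: %s (%d hit(s))\n",
              x$cluster_id, x$category, nrow(x$hits)))
  invisible(x)
}

#' Classify a set of clusters
#'
#' @param clusters named character vector of cluster sequences (e.g. from
#'   [read_clusters()]).
#' @param library list of [mature_mirna()] objects.
#' @param anchor 3'-end seed anchor.
#' @return List of `cluster_call` objects, named by cluster id.
#' @export
classify_clusters <- function(clusters, library, anchor = 14L) {
  ids <- names(clusters)
  if (is.null(ids)) ids <- paste0("cluster_", seq_along(clusters))
  out <- lapply(seq_along(clusters), function(i)
    classify_cluster(clusters[[i]], library, ids[i], anchor))
  stats::setNames(out, ids)
}

#' Summarize cluster calls
#'
#' Tallies clusters per category, and for the non-conventional-only clusters
#' counts the distinct miRNAs involved and the distinct transcripts hit
#' (when a cluster-to-transcript mapping is supplied).
#'
#' @param calls list of `cluster_call` objects.
#' @param mapping optional data.frame mapping `cluster_id` to
#'   `transcript_id`.
#' @return List with `by_category` (named integer vector over the four
#'   categories), `n_clusters`, `nonconv_mirnas`, `nonconv_transcripts`
#'   (`NA` when no mapping is given).
#' @export
summarize_clusters <- function(calls, mapping = NULL) {
  cats <- c("conventional_only", "nonconventional_only", "both", "none")
  got <- vapply(calls, function(x) x$category, character(1))
  by_category <- stats::setNames(
    vapply(cats, function(cc) sum(got == cc), integer(1)), cats)
  nonconv <- calls[got == "nonconventional_only"]
  mirnas <- unique(unlist(lapply(nonconv, function(x)
    x$hits$mirna_id[x$hits$mode %in% c("MIR3P", "CENTRAL")])))
  n_tx <- NA_integer_
  if (!is.null(mapping) && length(nonconv)) {
    ids <- vapply(nonconv, function(x) x$cluster_id, character(1))
    n_tx <- length(unique(
      mapping$transcript_id[mapping$cluster_id %in% ids]))
  } else if (!is.null(mapping)) n_tx <- 0L
  list(by_category = by_category, n_clusters = length(calls),
       nonconv_mirnas = length(mirnas), nonconv_transcripts = n_tx)
}

#' Write per-cluster calls as TSV
#' @param calls list of `cluster_call`s.
#' @param path output file (columns `cluster_id`, `category`, `n_hits`,
#'   `n_conventional`, `n_nonconventional`).
#' @return Invisibly, `path`.
#' @export
write_cluster_calls <- function(calls, path) {
  tab <- do.call(rbind, lapply(calls, function(x) data.frame(
    cluster_id = x$cluster_id, category = x$category,
    n_hits = nrow(x$hits),
    n_conventional = sum(x$hits$mode == "MIR5P"),
    n_nonconventional = sum(x$hits$mode %in% c("MIR3P", "CENTRAL")),
    stringsAsFactors = FALSE)))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
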