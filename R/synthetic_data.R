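# Seeded generators for every input the pipeline consumes, with planted
# ground truth. The central guarantee is the closed loop: for a generated
# transcript the scanner recovers exactly the planted 54-type count vector.
# This is achieved by (i) drawing background sequence free of any motif of
# the paired miRNA (rejection sampling), (ii) writing guard bases around
# each planted motif so it cannot be silently extended into a larger seed
# kind, and (iii) re-scanning after planting and redrawing on any residual
# collision (capped; exceeding the cap is a spec error).

random_rna <- function(n) paste(sample(RNA_BASES, n, replace = TRUE),
                                collapse = "")

# all target motifs a planted site could use: the 8 seed specs plus the
# central 11-mer window actually planted (s = 4)
mirna_motif_set <- function(seq, anchor = 14L) {
  sp <- seed_specs(anchor)
  ms <- list()
  for (i in seq_len(nrow(sp))) {
    if (nchar(seq) < sp$end[i]) next
    ms[[length(ms) + 1L]] <- list(
      mode = sp$mode[i],
      motif = seed_motif(substr(seq, sp$start[i], sp$end[i]),
                         sp$requires_A1[i], sp$a1_side[i]))
  }
  if (nchar(seq) >= 14L)
    ms[[length(ms) + 1L]] <- list(
      mode = "CENTRAL",
      motif = reverse_complement(substr(seq, 4L, 14L)))
  ms
}

# TRUE unless some motif of one pairing mode is a substring of a motif of
# another mode: such a miRNA cannot host unambiguous planted sites (planting
# the larger motif would always create a site of the other mode, which no
# redraw of the transcript can avoid)
mirna_motifs_clean <- function(seq, anchor = 14L) {
  ms <- mirna_motif_set(seq, anchor)
  for (a in ms) {
    for (b in ms) {
      if (a$mode != b$mode && grepl(b$motif, a$motif, fixed = TRUE))
        return(FALSE)
    }
  }
  TRUE
}

#' Generate a random mature miRNA
#'
#' 22-nt uniform-composition sequence, redrawn until no target motif of one
#' pairing mode (5'-end seed, 3'-end seed, central) is contained in a motif
#' of another mode, so that planted sites of the three modes can never be
#' confounded. In particular the 5'-end and 3'-end seed windows are
#' distinct, and neither seed motif is embedded in the central 11-mer.
#'
#' @param seed integer seed.
#' @param length miRNA length (default 22 nt).
#' @param anchor 3'-end seed anchor used for the motif checks.
#' @return A [mature_mirna()] with id `sim-mir-<seed>`.
#' @export
gen_mirna <- function(seed, length = 22L, anchor = 14L) {
  with_seed(seed, {
    repeat {
      s <- random_rna(length)
      if (mirna_motifs_clean(s, anchor)) break
    }
    mature_mirna(sprintf("sim-mir-%d", seed), s)
  })
}

# target motif and guard constraints for one planted site type.
# Guards are (offset relative to motif start, forbidden base) pairs that
# would otherwise upgrade the planted kind to a larger one.
planted_motif <- function(mirna, mode, kind, anchor = 14L) {
  seq <- mirna$seq
  if (mode == "CENTRAL") {
    s <- 4L  # any s in 2..9 covers positions 9-12; fixed for determinism
    return(list(motif = reverse_complement(substr(seq, s, s + 10L)),
                guards = list()))
  }
  sp <- seed_specs(anchor)
  row <- sp[sp$mode == mode & sp$kind == kind, ]
  motif <- seed_motif(substr(seq, row$start, row$end),
                      row$requires_A1, row$a1_side)
  len <- nchar(motif)
  comp1 <- function(b) chartr("ACGU", "UGCA", b)
  g <- list()
  if (mode == "MIR5P") {
    m8 <- comp1(substr(seq, 8L, 8L))
    if (kind == "6mer") g <- list(list(-1L, m8), list(len, "A"))
    if (kind == "7merA1") g <- list(list(-1L, m8))
    if (kind == "7merM8") g <- list(list(len, "A"))
  } else {
    m13 <- comp1(substr(seq, anchor - 1L, anchor - 1L))
    if (kind == "6mer") g <- list(list(len, m13), list(-1L, "A"))
    if (kind == "7merA1") g <- list(list(len, m13))
    if (kind == "7merM8") g <- list(list(-1L, "A"))
  }
  list(motif = motif, guards = g)
}

normalize_plan <- function(plan) {
  if (is.null(plan) || (is.data.frame(plan) && nrow(plan) == 0L))
    return(data.frame(region = character(0), mode = character(0),
                      kind = character(0), conserved = logical(0),
                      count = integer(0), stringsAsFactors = FALSE))
  stopifnot(is.data.frame(plan),
            all(c("region", "mode", "kind", "conserved") %in% names(plan)))
  if (is.null(plan$count)) plan$count <- 1L
  plan
}

plan_truth_vector <- function(plan) {
  truth <- empty_count_vector()
  for (i in seq_len(nrow(plan))) {
    idx <- site_type_index(plan$region[i], plan$mode[i], plan$kind[i],
                           plan$conserved[i])
    truth[idx] <- truth[idx] + as.integer(plan$count[i])
  }
  truth
}

#' Generate a transcript with planted target sites and ground truth
#'
#' Draws a motif-free background for each region, plants the sites named in
#' `plan` at seeded positions (guard bases prevent upgrades to larger seed
#' kinds), and emits conserved blocks (length >= 8) covering exactly the
#' sites planted as conserved. The result is verified by re-scanning:
#' generation is retried until the scanner's count vector equals the
#' planted truth exactly, and fails after `max_tries` attempts.
#'
#' @param mirna a [mature_mirna()] the sites are planted against.
#' @param plan data.frame with columns `region`, `mode`, `kind`,
#'   `conserved` and optional `count` (default 1). May be empty.
#' @param seed integer seed.
#' @param region_lengths named vector `c(utr5=, cds=, utr3=)` (defaults
#'   100/200/300 nt).
#' @param anchor 3'-end seed anchor.
#' @param max_tries rejection-sampling cap (default 1000).
#' @param id transcript id (default derived from the seed).
#' @return List with `transcript` (a [transcript_model()]), `truth` (the
#'   planted 54-vector), `blocks` (conserved-block data.frame, possibly
#'   empty) and `planted` (data.frame of planted positions).
#' @export
gen_transcript <- function(mirna, plan = NULL, seed,
                           region_lengths = c(utr5 = 100L, cds = 200L,
                                              utr3 = 300L),
                           anchor = 14L, max_tries = 1000L,
                           id = sprintf("sim-tx-%d", seed)) {
  plan <- normalize_plan(plan)
  truth <- plan_truth_vector(plan)
  # room check: each planted span needs at most 25 nt (longest motif plus
  # guards and spacing), plus boundary margins
  for (region in unique(plan$region)) {
    slot <- c(UTR5 = "utr5", ORF = "cds", UTR3 = "utr3")[[region]]
    need <- sum(plan$count[plan$region == region]) * 25L + 14L
    if (need > region_lengths[[slot]])
      stop(sprintf("region %s (%d nt) too short to host the plan", region,
                   region_lengths[[slot]]), call. = FALSE)
  }
  with_seed(seed, {
    for (try in seq_len(max_tries)) {
      tx <- transcript_model(id,
                             utr5 = random_rna(region_lengths[["utr5"]]),
                             cds = random_rna(region_lengths[["cds"]]),
                             utr3 = random_rna(region_lengths[["utr3"]]))
      if (sum(scan_pair(tx, mirna, NULL, anchor, align = FALSE)$counts) != 0L)
        next  # background must be motif-free
      res <- plant_sites(tx, mirna, plan, anchor)
      if (is.null(res)) next
      scan <- scan_pair(res$transcript, mirna, res$blocks, anchor,
                        align = FALSE)
      if (identical(unname(scan$counts), unname(truth)))
        return(list(transcript = res$transcript, truth = truth,
                    blocks = res$blocks, planted = res$planted))
    }
    stop(sprintf("could not realize the planted plan in %d tries", max_tries),
         call. = FALSE)
  })
}

# place all planted motifs; NULL on placement failure (caller redraws)
plant_sites <- function(tx, mirna, plan, anchor) {
  seqs <- list(UTR5 = tx$utr5, ORF = tx$cds, UTR3 = tx$utr3)
  used <- list(UTR5 = integer(0), ORF = integer(0), UTR3 = integer(0))
  planted <- list()
  blocks <- list()
  offsets <- region_offsets(tx)
  for (i in seq_len(nrow(plan))) {
    region <- plan$region[i]
    pm <- planted_motif(mirna, plan$mode[i], plan$kind[i], anchor)
    len <- nchar(pm$motif)
    rlen <- nchar(seqs[[region]])
    if (rlen - len - 7L < 8L) return(NULL)
    positions <- seq.int(8L, rlen - len - 7L)
    for (rep in seq_len(plan$count[i])) {
      ok <- FALSE
      for (attempt in 1:50) {
        # margin of 6 nt each side keeps guards, blocks and neighbours apart
        p <- positions[sample.int(length(positions), 1L)]
        span <- (p - 7L):(p + len + 6L)
        if (any(span %in% used[[region]])) next
        ok <- TRUE
        break
      }
      if (!ok) return(NULL)
      s <- seqs[[region]]
      substr(s, p, p + len - 1L) <- pm$motif
      ch <- strsplit(s, "", fixed = TRUE)[[1]]
      for (g in pm$guards) {
        pos <- p + g[[1]]
        if (pos >= 1L && pos <= rlen && ch[pos] == g[[2]]) {
          ch[pos] <- sample(setdiff(RNA_BASES, g[[2]]), 1L)
        }
      }
      seqs[[region]] <- paste(ch, collapse = "")
      used[[region]] <- c(used[[region]], span)
      start_tx <- p + offsets[[region]]
      end_tx <- start_tx + len - 1L
      planted[[length(planted) + 1L]] <- data.frame(
        region = region, mode = plan$mode[i], kind = plan$kind[i],
        conserved = plan$conserved[i], start_region = p,
        end_region = p + len - 1L, start_tx = start_tx, end_tx = end_tx,
        stringsAsFactors = FALSE)
      if (plan$conserved[i]) {
        # block covers the site and is at least 8 nt
        pad <- max(0L, 8L - len)
        blocks[[length(blocks) + 1L]] <- data.frame(
          transcript_id = tx$id, start = max(1L, start_tx - pad),
          end = end_tx, stringsAsFactors = FALSE)
      }
    }
  }
  bdf <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(transcript_id = character(0), start = integer(0),
               end = integer(0), stringsAsFactors = FALSE)
  if (nrow(bdf)) bdf$length <- bdf$end - bdf$start + 1L
  list(transcript = transcript_model(tx$id, seqs$UTR5, seqs$ORF, seqs$UTR3),
       blocks = bdf,
       planted = if (length(planted)) do.call(rbind, planted) else NULL)
}

#' Generate a synthetic fold-change dataset from a planted feature model
#'
#' Feature counts are drawn i.i.d. Poisson(`lambda`) per feature; the
#' response is `log2fc = -c * sigmoid(w* . x_norm + b*) + N(0, noise_sd)`,
#' clamped below zero (repression only), with `x_norm` the min-max
#' normalized features. The ground-truth weights are returned so parameter
#' recovery can be measured.
#'
#' @param n number of miRNA-target pairs.
#' @param seed integer seed.
#' @param w_star ground-truth weight vector (length 9); drawn
#'   Uniform(0.5, 2) when `NULL` (more sites, more repression).
#' @param b_star ground-truth bias (default -2).
#' @param noise_sd Gaussian noise on log2fc (default 0.02).
#' @param target_scale maximum repression magnitude `c` in log2 units
#'   (default 2).
#' @param lambda Poisson mean of the per-feature counts (default 0.7,
#'   giving count spectra dominated by 0-2 like real per-type site counts).
#' @return List with `features` (n x 9 matrix), `log2fc`, `w_star`,
#'   `b_star`, `target_scale`, `noise_sd`.
#' @export
gen_foldchange_dataset <- function(n, seed, w_star = NULL, b_star = -2,
                                   noise_sd = 0.02, target_scale = 2,
                                   lambda = 0.7) {
  stopifnot(noise_sd >= 0)
  with_seed(seed, {
    if (is.null(w_star)) w_star <- stats::runif(9, 0.5, 2)
    x <- matrix(stats::rpois(n * 9L, lambda), n, 9L,
                dimnames = list(NULL, FEATURE_LABELS))
    xn <- normalize_features(check_feature_matrix(x))$x
    mu <- -target_scale * stats::plogis(as.numeric(xn %*% w_star) + b_star)
    y <- pmin(mu + stats::rnorm(n, 0, noise_sd), -1e-6)
    list(features = x, log2fc = y, w_star = w_star, b_star = b_star,
         target_scale = target_scale, noise_sd = noise_sd)
  })
}

#' Generate a screen dataset with at most one informative site type
#'
#' Used for the correlation screen's operating characteristics. Counts of
#' all 54 types are i.i.d. Poisson(`lambda`); the response is
#' `log2fc = -(0.5 + beta * count[, effect_index]) + N(0, sd)`. With
#' `beta = 0` (default) fold change is independent of every count: the null
#' configuration for type-I error measurement.
#'
#' @param n number of records.
#' @param seed integer seed.
#' @param effect_index canonical type index (1..54) of the informative
#'   type, or `NULL` for the null.
#' @param beta per-site repression effect in log2 units (default 0).
#' @param lambda Poisson mean of the counts (default 1).
#' @param sd response noise (default 0.3).
#' @return List with `counts` (n x 54 matrix) and `log2fc`.
#' @export
gen_screen_dataset <- function(n, seed, effect_index = NULL, beta = 0,
                               lambda = 1, sd = 0.3) {
  with_seed(seed, {
    counts <- matrix(stats::rpois(n * 54L, lambda), n, 54L,
                     dimnames = list(NULL, site_types_cached()$label))
    mu <- rep(-0.5, n)
    if (!is.null(effect_index))
      mu <- mu - beta * counts[, effect_index]
    list(counts = counts, log2fc = mu + stats::rnorm(n, 0, sd))
  })
}

# small random plan over plantable types
random_plan <- function(n_sites, mirna_length = 22L) {
  st <- site_types_cached()  # all 54 types are plantable
  pick <- st[sample.int(nrow(st), n_sites, replace = TRUE), ]
  plan <- pick[c("region", "mode", "kind", "conserved")]
  plan$count <- rep(1L, nrow(plan))
  rownames(plan) <- NULL
  plan
}

#' Write a complete synthetic fixture set to disk
#'
#' Generates one miRNA and `n_transcripts` transcripts with random planted
#' plans, plus a fold-change table over the planted feature model, and
#' writes: miRNA FASTA, transcript FASTA + region TSV, conserved-block BED,
#' fold-change TSV and a planted-truth TSV (the 54 counts per transcript).
#'
#' @param dir output directory (created if missing).
#' @param seed integer seed.
#' @param n_transcripts number of transcripts (default 10).
#' @param max_sites maximum planted sites per transcript (default 3).
#' @return Invisibly, a named vector of the file paths.
#' @export
simulate_fixtures <- function(dir, seed, n_transcripts = 10L,
                              max_sites = 3L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  mir <- gen_mirna(seed)
  txs <- vector("list", n_transcripts)
  truths <- matrix(0L, n_transcripts, 54L,
                   dimnames = list(NULL, site_types_cached()$label))
  blocks <- list()
  plans <- with_seed(seed + 1L, lapply(seq_len(n_transcripts), function(i)
    random_plan(sample.int(max_sites + 1L, 1L) - 1L)))
  for (i in seq_len(n_transcripts)) {
    g <- gen_transcript(mir, plans[[i]], seed = seed + 10L + i)
    txs[[i]] <- g$transcript
    truths[i, ] <- g$truth
    if (nrow(g$blocks)) blocks[[length(blocks) + 1L]] <- g$blocks
  }
  paths <- c(mirna_fasta = file.path(dir, "mirna.fa"),
             transcript_fasta = file.path(dir, "transcripts.fa"),
             regions_tsv = file.path(dir, "regions.tsv"),
             blocks_bed = file.path(dir, "conserved.bed"),
             foldchange_tsv = file.path(dir, "foldchange.tsv"),
             truth_tsv = file.path(dir, "truth.tsv"))
  Biostrings::writeXStringSet(
    Biostrings::BStringSet(stats::setNames(mir$seq, mir$id)),
    paths[["mirna_fasta"]])
  write_transcripts(txs, paths[["transcript_fasta"]], paths[["regions_tsv"]])
  bed <- if (length(blocks)) do.call(rbind, blocks) else
    data.frame(transcript_id = character(0), start = integer(0),
               end = integer(0))
  writeLines(sprintf("%s\t%d\t%d", bed$transcript_id, bed$start - 1L,
                     bed$end), paths[["blocks_bed"]])
  fc <- gen_foldchange_dataset(n_transcripts, seed + 2L)
  fc_tab <- data.frame(mirna_id = mir$id,
                       transcript_id = vapply(txs, `[[`, character(1), "id"),
                       log2fc = fc$log2fc[seq_len(n_transcripts)])
  utils::write.table(fc_tab, paths[["foldchange_tsv"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  truth_tab <- data.frame(
    transcript_id = vapply(txs, `[[`, character(1), "id"), truths,
    check.names = FALSE)
  utils::write.table(truth_tab, paths[["truth_tsv"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}
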