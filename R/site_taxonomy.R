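# The closed 54-type site taxonomy and its projection onto the 9 regression
# features. The serial order of the 54 types is the canonical index of every
# count vector produced by the package, so output columns are stable:
# rows 1-48 are region blocks UTR3, ORF, UTR5; within a region, miRNA 5'-end
# kinds then miRNA 3'-end kinds; within an end, 6mer / 7merA1 / 7merM8 / 8mer,
# each conserved before non-conserved. Rows 49-54 are the central 11-mer
# types, again UTR3 / ORF / UTR5, conserved before non-conserved.

SEED_KINDS <- c("6mer", "7merA1", "7merM8", "8mer")

region_mnemonic <- c(UTR3 = "3U", ORF = "ORF", UTR5 = "5U")
mode_mnemonic <- c(MIR5P = "5P", MIR3P = "3P", CENTRAL = "Central")

site_type_label <- function(region, mode, kind, conserved) {
  paste0(region_mnemonic[region], mode_mnemonic[mode], kind,
         ifelse(conserved, "_cons", "_noncons"))
}

#' Enumerate the 54 miRNA target-site types
#'
#' The taxonomy crosses target region (3' UTR, ORF, 5' UTR), miRNA pairing
#' mode (5'-end seed, 3'-end seed, central), seed kind (6mer, 7merA1,
#' 7merM8, 8mer for the end modes; a single 11-mer kind for central) and
#' conservation status: 3 x 2 x 4 x 2 + 3 x 1 x 2 = 54 types. Row order is
#' fixed and is the index of every 54-entry count vector in the package.
#'
#' @return data.frame with 54 rows and columns `index`, `region`
#'   (`UTR3`/`ORF`/`UTR5`), `mode` (`MIR5P`/`MIR3P`/`CENTRAL`), `kind`
#'   (`6mer`/`7merA1`/`7merM8`/`8mer`/`11mer`), `conserved` (logical) and
#'   `label` (the serialization mnemonic, e.g. `"3U3P7merM8_noncons"`).
#' @export
site_types <- function() {
  rows <- list()
  for (region in c("UTR3", "ORF", "UTR5")) {
    for (mode in c("MIR5P", "MIR3P")) {
      for (kind in SEED_KINDS) {
        for (conserved in c(TRUE, FALSE)) {
          rows[[length(rows) + 1L]] <- list(region, mode, kind, conserved)
        }
      }
    }
  }
  for (region in c("UTR3", "ORF", "UTR5")) {
    for (conserved in c(TRUE, FALSE)) {
      rows[[length(rows) + 1L]] <- list(region, "CENTRAL", "11mer", conserved)
    }
  }
  df <- data.frame(
    index = seq_along(rows),
    region = vapply(rows, `[[`, character(1), 1),
    mode = vapply(rows, `[[`, character(1), 2),
    kind = vapply(rows, `[[`, character(1), 3),
    conserved = vapply(rows, `[[`, logical(1), 4),
    stringsAsFactors = FALSE)
  df$label <- site_type_label(df$region, df$mode, df$kind, df$conserved)
  rownames(df) <- NULL
  df
}

.SITE_TYPES <- NULL
site_types_cached <- function() {
  if (is.null(.SITE_TYPES)) {
    # assigned once per session; site_types() is cheap but called in loops
    utils::assignInMyNamespace(".SITE_TYPES", site_types())
  }
  .SITE_TYPES
}

#' Index of a site type in the canonical 54-type order
#'
#' @param region `"UTR3"`, `"ORF"` or `"UTR5"`.
#' @param mode `"MIR5P"`, `"MIR3P"` or `"CENTRAL"`.
#' @param kind `"6mer"`, `"7merA1"`, `"7merM8"`, `"8mer"` or `"11mer"`.
#' @param conserved logical.
#' @return Integer in 1..54. Vectorized over its arguments.
#' @export
site_type_index <- function(region, mode, kind, conserved) {
  st <- site_types_cached()
  key <- paste(region, mode, kind, conserved)
  idx <- match(key, paste(st$region, st$mode, st$kind, st$conserved))
  if (anyNA(idx)) stop("unknown site type: ", key[which(is.na(idx))[1]],
                       call. = FALSE)
  idx
}

# The nine site types retained for the repression regression, in the fixed
# feature order. Only these counts enter the network; all other types are
# dropped (never summed into a feature).
FEATURE_LABELS <- c(
  "3U5P6mer_cons", "3U5P6mer_noncons", "3U5P7merA1_noncons",
  "3U5P7merM8_noncons", "3U3P6mer_noncons", "3U3P7merM8_noncons",
  "ORF5P6mer_noncons", "ORF3P6mer_noncons", "5U5P6mer_noncons")

#' The 9 site types used as regression features
#'
#' These are the types whose counts showed a significant correlation with
#' protein fold change (raw p < 0.05 screen); their order is the input order
#' of the 9-4-1 network.
#'
#' @return data.frame: the 9 corresponding rows of [site_types()], with a
#'   `feature` column giving the feature position 1..9.
#' @export
feature_types <- function() {
  st <- site_types_cached()
  rows <- st[match(FEATURE_LABELS, st$label), ]
  rows$feature <- seq_len(nrow(rows))
  rownames(rows) <- NULL
  rows
}

#' Feature position of a site type, or NA if not retained
#'
#' @inheritParams site_type_index
#' @return Integer in 1..9, or `NA_integer_` for the 45 types that are not
#'   regression features.
#' @export
feature_index <- function(region, mode, kind, conserved) {
  lab <- site_type_label(region, mode, kind, conserved)
  # validate the type exists before looking it up among the 9
  site_type_index(region, mode, kind, conserved)
  match(lab, FEATURE_LABELS)
}

#' Project a 54-type count vector onto the 9 regression features
#'
#' A pure projection: feature i is the count of the i-th retained type;
#' counts of non-retained types are dropped, never aggregated.
#'
#' @param counts numeric vector of length 54 in canonical type order (or a
#'   matrix with 54 columns; rows are miRNA-target pairs).
#' @return Numeric vector of length 9 (or matrix with 9 columns), named by
#'   feature label.
#' @export
project_features <- function(counts) {
  idx <- match(FEATURE_LABELS, site_types_cached()$label)
  if (is.matrix(counts)) {
    if (ncol(counts) != 54L)
      stop("count matrix must have 54 columns", call. = FALSE)
    out <- counts[, idx, drop = FALSE]
    colnames(out) <- FEATURE_LABELS
    return(out)
  }
  if (length(counts) != 54L)
    stop("count vector must have length 54", call. = FALSE)
  stats::setNames(counts[idx], FEATURE_LABELS)
}

#' Zero count vector in canonical 54-type order
#' @return Named integer vector of length 54.
#' @export
empty_count_vector <- function() {
  stats::setNames(integer(54), site_types_cached()$label)
}
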