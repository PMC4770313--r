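# The 54-type correlation screen against protein fold changes and the
# cumulative-distribution comparisons used to contrast site-type cohorts.

#' Pearson correlation with t-based significance
#'
#' Sample Pearson r with the two-sided p-value from the t transform
#' t = r * sqrt((n-2)/(1-r^2)) on n-2 degrees of freedom (as in
#' [stats::cor.test()], which does the work here).
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return List with `r`, `p`, `n`.
#' @export
pearson_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y differ in length", call. = FALSE)
  if (length(x) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0)
    stop("undefined correlation: zero variance", call. = FALSE)
  ct <- stats::cor.test(x, y, method = "pearson", alternative = "two.sided")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x))
}

#' Correlation screen of all 54 site types against fold change
#'
#' For every site type, correlates its per-pair count with the repression
#' response across the dataset. With `response = "magnitude"` (default) the
#' response is `-log2fc`, so that more sites associating with stronger
#' repression yields a positive coefficient; `response = "log2fc"` uses the
#' raw fold change (signs flip). Types whose count column is constant get
#' `NA` coefficients flagged `defined = FALSE` rather than failing. No
#' multiple-testing correction is applied: the screen is a raw p < 0.05
#' filter by design.
#'
#' @param counts matrix with 54 columns in canonical type order (rows are
#'   miRNA-target pairs), or a list of 54-vectors.
#' @param log2fc numeric vector of log2 protein fold changes (one per row).
#' @param response `"magnitude"` or `"log2fc"`.
#' @param alpha significance threshold (default 0.05).
#' @return data.frame with 54 rows in canonical order: `site_type_label`,
#'   `r`, `p`, `n`, `defined`, `significant`.
#' @export
screen_site_types <- function(counts, log2fc,
                              response = c("magnitude", "log2fc"),
                              alpha = 0.05) {
  response <- match.arg(response)
  if (is.list(counts) && !is.data.frame(counts))
    counts <- do.call(rbind, counts)
  counts <- as.matrix(counts)
  if (ncol(counts) != 54L)
    stop("counts must have 54 columns in canonical type order",
         call. = FALSE)
  if (nrow(counts) != length(log2fc))
    stop("counts and log2fc disagree in length", call. = FALSE)
  if (nrow(counts) < 3L) stop("need at least 3 records", call. = FALSE)
  y <- if (response == "magnitude") -log2fc else log2fc
  st <- site_types_cached()
  r <- p <- rep(NA_real_, 54L)
  defined <- rep(FALSE, 54L)
  for (j in seq_len(54L)) {
    cj <- counts[, j]
    if (stats::sd(cj) == 0 || stats::sd(y) == 0) next
    res <- pearson_cor(cj, y)
    r[j] <- res$r; p[j] <- res$p; defined[j] <- TRUE
  }
  data.frame(site_type_label = st$label, r = r, p = p,
             n = nrow(counts), defined = defined,
             significant = defined & !is.na(p) & p < alpha,
             stringsAsFactors = FALSE)
}

#' Compare two fold-change cohorts by their cumulative distributions
#'
#' Two-sample ECDFs plus the Kolmogorov-Smirnov D statistic and asymptotic
#' p-value. Typical cohorts: targets carrying exactly one site of a named
#' class (and no other site of any class) versus targets with no site at
#' all.
#'
#' @param group_a,group_b numeric vectors (log2 fold changes), non-empty.
#' @param labels character vector of two cohort names.
#' @return Object of class `ecdf_comparison`: sorted values and cumulative
#'   fractions per group, `D`, `p`.
#' @export
ecdf_compare <- function(group_a, group_b,
                         labels = c("group_a", "group_b")) {
  if (!length(group_a) || !length(group_b))
    stop("both groups must be non-empty", call. = FALSE)
  ks <- suppressWarnings(stats::ks.test(group_a, group_b))
  mk <- function(v) {
    v <- sort(v)
    data.frame(value = v, cumulative_fraction = seq_along(v) / length(v))
  }
  structure(list(labels = labels, a = mk(group_a), b = mk(group_b),
                 D = unname(ks$statistic), p = ks$p.value),
            class = "ecdf_comparison")
}

#' @export
print.ecdf_comparison <- function(x, ...) {
  cat(sprintf("<ecdf_comparison> %s (n=%d) vs %s (n=%d)\n",
              x$labels[1], nrow(x$a), x$labels[2], nrow(x$b)))
  cat(sprintf("  KS D = %.4f, p = %.3g\n", x$D, x$p))
  invisible(x)
}

#' @export
plot.ecdf_comparison <- function(x, ...) {
  rng <- range(x$a$value, x$b$value)
  graphics::plot(stats::ecdf(x$a$value), xlim = rng, col = "red",
                 main = "cumulative distribution of log2 fold change",
                 xlab = "log2 fold change", ylab = "cumulative fraction",
                 ...)
  graphics::lines(stats::ecdf(x$b$value), col = "blue")
  graphics::legend("topleft", legend = x$labels, col = c("red", "blue"),
                   lty = 1, bty = "n")
  invisible(x)
}

#' Write ECDF curves as a long-format TSV
#' @param cmp an `ecdf_comparison`.
#' @param path output file (columns `value`, `cumulative_fraction`,
#'   `group`).
#' @return Invisibly, `path`.
#' @export
write_ecdf <- function(cmp, path) {
  stopifnot(inherits(cmp, "ecdf_comparison"))
  long <- rbind(cbind(cmp$a, group = cmp$labels[1]),
                cbind(cmp$b, group = cmp$labels[2]))
  utils::write.table(long, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Select one-site-only cohorts from a count matrix
#'
#' Returns the row indices of pairs carrying exactly one site of the named
#' type classes and zero sites of every other class; the no-site cohort is
#' the all-zero rows.
#'
#' @param counts matrix with 54 columns in canonical order.
#' @param labels site-type labels defining the class (counts are summed
#'   across the named columns; e.g. both conservation states of one type).
#' @return List with `one_site` and `no_site` integer index vectors.
#' @export
cohort_indices <- function(counts, labels) {
  counts <- as.matrix(counts)
  st <- site_types_cached()
  sel <- match(labels, st$label)
  if (anyNA(sel)) stop("unknown site-type label(s): ",
                       paste(labels[is.na(sel)], collapse = ", "),
                       call. = FALSE)
  inside <- rowSums(counts[, sel, drop = FALSE])
  outside <- rowSums(counts[, -sel, drop = FALSE])
  list(one_site = which(inside == 1L & outside == 0L),
       no_site = which(inside == 0L & outside == 0L))
}
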