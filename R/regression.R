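# The repression regressor: a 9-4-1 feedforward network (logistic sigmoid in
# both layers) mapping the nine informative site-type counts to a repression
# score in (0,1). Training targets are negative log2 protein fold changes
# rescaled to (0,1) by the training set's maximum repression magnitude c:
# y = -log2fc / c, so that -score * c recovers fold-change units. Training
# is online backpropagation (Rcpp inner loop) with seeded initialization.

# restore the caller's RNG state after seeded work
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

check_feature_matrix <- function(x) {
  if (is.data.frame(x)) {
    if (all(FEATURE_LABELS %in% names(x))) x <- x[FEATURE_LABELS]
    x <- as.matrix(x)
  }
  if (is.null(dim(x))) x <- matrix(x, nrow = 1L)
  if (ncol(x) == 54L) x <- project_features(x)
  if (ncol(x) != 9L)
    stop("feature input must have 9 columns (or 54 to be projected)",
         call. = FALSE)
  storage.mode(x) <- "double"
  colnames(x) <- FEATURE_LABELS
  x
}

normalize_features <- function(x, norm = NULL) {
  if (is.null(norm)) {
    lo <- apply(x, 2, min)
    hi <- apply(x, 2, max)
    span <- hi - lo
    span[span == 0] <- 1  # constant feature: mapped to 0, never divides by 0
    norm <- list(min = lo, span = span)
  }
  xn <- sweep(sweep(x, 2, norm$min, "-"), 2, norm$span, "/")
  list(x = xn, norm = norm)
}

#' Fit the repression network to site-type features and fold changes
#'
#' Fits a 9 x `hidden` x 1 sigmoid network by online backpropagation.
#' `log2fc` must be strictly negative (repressed targets only; apply the
#' negative-fold-change filter upstream, e.g. via [read_foldchange()]).
#' Targets are `-log2fc / c` with `c = max(|log2fc|)`, clipped to
#' `(clip, 1 - clip)`; inputs are min-max normalized per feature over the
#' training set. Weights are initialized Uniform(-0.5, 0.5) from `seed` and
#' examples are presented in one seeded shuffle reused across epochs, so two
#' fits with the same seed are bit-identical.
#'
#' @param x feature input: matrix/data.frame with the 9 feature columns (54
#'   columns are projected automatically).
#' @param log2fc numeric vector of log2 protein fold changes, all `< 0`.
#' @param hidden hidden-layer width (default 4).
#' @param learning_rate online learning rate (default 0.01).
#' @param epochs passes over the data (default 1000).
#' @param seed integer RNG seed (required: the fit contract is seeded
#'   determinism).
#' @param clip target clipping margin in (0, 0.5) (default 0.01).
#' @return Object of class `repress_ann` with weights (`w_hidden` `hidden x
#'   9`, `b_hidden`, `w_out`, `b_out`), the input normalization, the target
#'   scale `c`, the config, and training fit (`fitted`, `residuals` in
#'   log2-fold-change units).
#' @seealso [predict.repress_ann()], [cross_validate()],
#'   [predict_repression()]
#' @export
ann_fit <- function(x, log2fc, hidden = 4L, learning_rate = 0.01,
                    epochs = 1000L, seed, clip = 0.01) {
  x <- check_feature_matrix(x)
  if (length(log2fc) != nrow(x))
    stop("x and log2fc disagree in length", call. = FALSE)
  if (nrow(x) == 0L) stop("empty training data", call. = FALSE)
  if (any(!is.finite(log2fc)) || any(log2fc >= 0))
    stop("all log2fc must be finite and < 0 (repressed targets only)",
         call. = FALSE)
  if (missing(seed)) stop("a seed is required for reproducible training",
                          call. = FALSE)
  cmax <- max(abs(log2fc))
  if (cmax == 0) stop("target scale is zero", call. = FALSE)
  t <- pmin(pmax(-log2fc / cmax, clip), 1 - clip)
  nf <- normalize_features(x)

  p <- ncol(x); h <- as.integer(hidden); n <- nrow(x)
  init <- with_seed(seed, {
    list(W1 = matrix(stats::runif(h * p, -0.5, 0.5), h, p),
         b1 = stats::runif(h, -0.5, 0.5),
         w2 = stats::runif(h, -0.5, 0.5),
         b2 = stats::runif(1, -0.5, 0.5),
         order = sample.int(n) - 1L)
  })
  fit <- ann_backprop(nf$x, t, init$W1, init$b1, init$w2, init$b2,
                      learning_rate, as.integer(epochs), init$order)
  model <- structure(list(
    w_hidden = fit$W1, b_hidden = as.numeric(fit$b1),
    w_out = as.numeric(fit$w2), b_out = as.numeric(fit$b2),
    norm = nf$norm, target_scale = cmax,
    config = list(hidden = h, learning_rate = learning_rate,
                  epochs = as.integer(epochs), clip = clip),
    seed = as.integer(seed), n_train = n,
    feature_labels = FEATURE_LABELS),
    class = "repress_ann")
  scores <- ann_forward(model, x)
  model$fitted_score <- scores
  model$fitted <- -scores * cmax
  model$residuals <- log2fc - model$fitted
  model$train_rmse <- sqrt(mean(model$residuals^2))
  model
}

#' Forward pass of the repression network
#'
#' @param model a `repress_ann`.
#' @param x feature matrix (see [ann_fit()]).
#' @return Numeric vector of repression scores in (0,1).
#' @export
ann_forward <- function(model, x) {
  x <- check_feature_matrix(x)
  xn <- normalize_features(x, model$norm)$x
  H <- stats::plogis(xn %*% t(model$w_hidden) +
                       matrix(model$b_hidden, nrow(xn), length(model$b_hidden),
                              byrow = TRUE))
  as.numeric(stats::plogis(H %*% model$w_out + model$b_out))
}

#' @export
print.repress_ann <- function(x, ...) {
  cat(sprintf(
    "<repress_ann> %d-%d-1 sigmoid network, %d training pairs\n",
    ncol(x$w_hidden), x$config$hidden, x$n_train))
  cat(sprintf("  learning rate %.3g, %d epochs, seed %d\n",
              x$config$learning_rate, x$config$epochs, x$seed))
  cat(sprintf("  target scale c = %.4g (predicted log2fc = -score * c)\n",
              x$target_scale))
  cat(sprintf("  training RMSE %.4g (log2 fold-change units)\n",
              x$train_rmse))
  invisible(x)
}

#' @export
summary.repress_ann <- function(object, ...) {
  res <- object$residuals
  out <- list(model = object,
              residual_summary = summary(res),
              train_rmse = object$train_rmse,
              train_cor = stats::cor(object$fitted, object$fitted + res))
  class(out) <- "summary.repress_ann"
  out
}

#' @export
print.summary.repress_ann <- function(x, ...) {
  print(x$model)
  cat(sprintf("  training Pearson r (predicted vs observed log2fc): %.3f\n",
              x$train_cor))
  cat("  residuals (log2fc units):\n")
  print(x$residual_summary)
  invisible(x)
}

#' @export
coef.repress_ann <- function(object, ...) {
  list(w_hidden = object$w_hidden, b_hidden = object$b_hidden,
       w_out = object$w_out, b_out = object$b_out)
}

#' Predict repression from site-type features
#'
#' @param object a `repress_ann`.
#' @param newdata feature matrix/data.frame (9 or 54 columns); defaults to
#'   the training fit.
#' @param type `"score"` for the (0,1) repression score, `"log2fc"` for the
#'   back-transformed log2 fold change `-score * c`.
#' @param ... unused.
#' @return Numeric vector.
#' @export
predict.repress_ann <- function(object, newdata = NULL,
                                type = c("score", "log2fc"), ...) {
  type <- match.arg(type)
  score <- if (is.null(newdata)) object$fitted_score
           else ann_forward(object, newdata)
  if (type == "score") score else -score * object$target_scale
}

#' @export
fitted.repress_ann <- function(object, ...) object$fitted

#' @export
residuals.repress_ann <- function(object, ...) object$residuals

#' Observed-versus-predicted plot for a fitted repression network
#' @param x a `repress_ann`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.repress_ann <- function(x, ...) {
  obs <- x$fitted + x$residuals
  graphics::plot(x$fitted, obs,
                 xlab = "predicted log2 fold change",
                 ylab = "observed log2 fold change",
                 main = "repress_ann fit", ...)
  graphics::abline(0, 1, lty = 2)
  invisible(x)
}

#' Simulate fold changes from a fitted repression network
#'
#' Draws `nsim` replicates of the training response: predicted log2 fold
#' change plus Gaussian noise with the residual standard deviation, clamped
#' below zero (repression only).
#'
#' @param object a `repress_ann`.
#' @param nsim number of replicates.
#' @param seed integer seed.
#' @param ... unused.
#' @return data.frame with `nsim` columns of simulated log2fc.
#' @export
simulate.repress_ann <- function(object, nsim = 1, seed = NULL, ...) {
  sdres <- stats::sd(object$residuals)
  n <- length(object$fitted)
  sim <- function() pmin(object$fitted + stats::rnorm(n, 0, sdres), -1e-6)
  draw <- function() as.data.frame(
    stats::setNames(replicate(nsim, sim(), simplify = FALSE),
                    paste0("sim_", seq_len(nsim))))
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' k-fold cross-validation of the repression network
#'
#' Records are shuffled once (seeded) and dealt into `k` near-equal folds
#' that partition the data. For each fold the network is trained on the
#' remaining records and evaluated on the held-out fold; RMSE is computed on
#' predicted versus observed log2 fold change, back-transformed through each
#' training split's own target scale `c`.
#'
#' @param x,log2fc as in [ann_fit()].
#' @param k number of folds (default 10).
#' @param seed integer seed controlling the fold assignment and every fold's
#'   training run.
#' @param ... passed to [ann_fit()] (`hidden`, `learning_rate`, `epochs`).
#' @return Object of class `repress_cv`: `fold_rmse` (length `k`),
#'   `mean_rmse`, `fold_id` (test-fold index of every record), `k`, `seed`.
#' @export
cross_validate <- function(x, log2fc, k = 10L, seed, ...) {
  x <- check_feature_matrix(x)
  n <- nrow(x)
  if (n < k) stop(sprintf("need at least k = %d records, got %d", k, n),
                  call. = FALSE)
  if (missing(seed)) stop("a seed is required", call. = FALSE)
  perm <- with_seed(seed, sample.int(n))
  fold_id <- integer(n)
  fold_id[perm] <- rep_len(seq_len(k), n)
  fold_rmse <- numeric(k)
  for (f in seq_len(k)) {
    test <- fold_id == f
    fit <- ann_fit(x[!test, , drop = FALSE], log2fc[!test],
                   seed = seed + f, ...)
    pred <- predict(fit, x[test, , drop = FALSE], type = "log2fc")
    fold_rmse[f] <- sqrt(mean((log2fc[test] - pred)^2))
  }
  structure(list(fold_rmse = fold_rmse, mean_rmse = mean(fold_rmse),
                 fold_id = fold_id, k = k, seed = as.integer(seed)),
            class = "repress_cv")
}

#' @export
print.repress_cv <- function(x, ...) {
  cat(sprintf("<repress_cv> %d-fold cross-validation (seed %d)\n",
              x$k, x$seed))
  cat(sprintf("  mean RMSE %.4g (log2 fold-change units)\n", x$mean_rmse))
  cat("  per fold:", paste(sprintf("%.3g", x$fold_rmse), collapse = " "),
      "\n")
  invisible(x)
}

#' Predict repression for a miRNA-transcript pair
#'
#' The end-to-end composition: scan the pair for all site types, project the
#' 54-type count vector onto the 9 features, and run the fitted network. The
#' returned site list is exactly the scanner's output.
#'
#' @param transcript a [transcript_model()].
#' @param mirna a [mature_mirna()].
#' @param model a fitted `repress_ann`.
#' @param blocks conserved blocks (see [scan_pair()]), or `NULL`.
#' @param anchor 3'-end seed anchor.
#' @return List with `score` (repression score in (0,1)),
#'   `predicted_log2fc` (`-score * c`), `sites` (data.frame) and `counts`
#'   (the 54-vector).
#' @export
predict_repression <- function(transcript, mirna, model, blocks = NULL,
                               anchor = 14L) {
  stopifnot(inherits(model, "repress_ann"))
  scan <- scan_pair(transcript, mirna, blocks, anchor)
  feats <- project_features(scan$counts)
  score <- ann_forward(model, matrix(feats, nrow = 1L))
  list(score = score, predicted_log2fc = -score * model$target_scale,
       sites = scan$sites, counts = scan$counts)
}

#' Serialize a fitted repression network to JSON
#'
#' @param model a `repress_ann`.
#' @param path output file.
#' @return Invisibly, `path`.
#' @export
write_ann <- function(model, path) {
  stopifnot(inherits(model, "repress_ann"))
  doc <- list(w_hidden = model$w_hidden, b_hidden = model$b_hidden,
              w_out = model$w_out, b_out = model$b_out,
              norm_min = model$norm$min, norm_span = model$norm$span,
              target_scale = model$target_scale, config = model$config,
              seed = model$seed, n_train = model$n_train,
              feature_labels = model$feature_labels)
  jsonlite::write_json(doc, path, digits = NA, auto_unbox = TRUE,
                       matrix = "rowmajor")
  invisible(path)
}

#' Load a repression network from JSON
#'
#' @param path file written by [write_ann()].
#' @return A `repress_ann` (without training-fit fields).
#' @export
read_ann <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  w1 <- as.matrix(doc$w_hidden)
  dimnames(w1) <- NULL
  structure(list(
    w_hidden = w1,
    b_hidden = as.numeric(doc$b_hidden),
    w_out = as.numeric(doc$w_out), b_out = as.numeric(doc$b_out),
    norm = list(min = stats::setNames(as.numeric(doc$norm_min),
                                      doc$feature_labels),
                span = stats::setNames(as.numeric(doc$norm_span),
                                       doc$feature_labels)),
    target_scale = doc$target_scale,
    config = doc$config, seed = doc$seed, n_train = doc$n_train,
    feature_labels = doc$feature_labels,
    train_rmse = NA_real_),
    class = "repress_ann")
}
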