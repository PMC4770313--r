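# hand-built model: identity normalization, chosen weights
manual_model <- function(w_hidden, b_hidden, w_out, b_out, c = 1) {
  structure(list(
    w_hidden = w_hidden, b_hidden = b_hidden, w_out = w_out, b_out = b_out,
    norm = list(min = stats::setNames(rep(0, 9), mirsite:::FEATURE_LABELS),
                span = stats::setNames(rep(1, 9), mirsite:::FEATURE_LABELS)),
    target_scale = c,
    config = list(hidden = nrow(w_hidden), learning_rate = 0.01,
                  epochs = 0L, clip = 0.01),
    seed = 0L, n_train = 0L, feature_labels = mirsite:::FEATURE_LABELS),
    class = "repress_ann")
}

test_that("the forward pass matches hand computation", {
  zero <- manual_model(matrix(0, 4, 9), rep(0, 4), rep(0, 4), 0)
  x <- matrix(rpois(9, 1), 1, 9)
  expect_equal(ann_forward(zero, x), 0.5)

  # hidden unit 1 at sigma(0)=0.5 drives the output through w_out=(1,0,0,0)
  m <- manual_model(matrix(0, 4, 9), rep(0, 4), c(1, 0, 0, 0), 0)
  expect_equal(ann_forward(m, x), plogis(0.5), tolerance = 1e-12)
  expect_equal(plogis(0.5), 0.6224593, tolerance = 1e-6)

  # determinism: same model, same input, same score
  expect_identical(ann_forward(m, x), ann_forward(m, x))
  expect_error(ann_forward(m, matrix(0, 1, 5)), "9 columns")
})

test_that("training is seeded and bit-reproducible", {
  d <- gen_foldchange_dataset(60, seed = 4)
  f1 <- ann_fit(d$features, d$log2fc, seed = 9, epochs = 50)
  f2 <- ann_fit(d$features, d$log2fc, seed = 9, epochs = 50)
  expect_identical(coef(f1), coef(f2))
  expect_identical(f1$fitted, f2$fitted)
  f3 <- ann_fit(d$features, d$log2fc, seed = 10, epochs = 50)
  expect_false(identical(coef(f1), coef(f3)))
})

test_that("training input is validated", {
  d <- gen_foldchange_dataset(20, seed = 4)
  expect_error(ann_fit(d$features[0, ], numeric(0), seed = 1), "empty")
  expect_error(ann_fit(d$features, abs(d$log2fc), seed = 1), "< 0")
  expect_error(ann_fit(d$features, d$log2fc), "seed")
})

test_that("a single example is fit to within 0.05", {
  x <- matrix(c(2, 1, 0, 3, 0, 0, 1, 0, 0), 1, 9)
  fit <- ann_fit(x, -1, seed = 3, epochs = 20000)
  pred <- predict(fit, x, type = "log2fc")
  expect_lt(abs(pred - (-1)), 0.05)
})

test_that("output is bounded and the log2fc transform is exact", {
  d <- gen_foldchange_dataset(200, seed = 21)
  fit <- ann_fit(d$features, d$log2fc, seed = 5, epochs = 100)
  s <- predict(fit, d$features, type = "score")
  expect_true(all(s > 0 & s < 1))
  expect_identical(predict(fit, d$features, type = "log2fc"),
                   -s * fit$target_scale)
  expect_true(all(predict(fit, d$features, type = "log2fc") <= 0))
})

test_that("the network recovers a planted feature-response model", {
  d <- gen_foldchange_dataset(1200, seed = 31)
  train <- 1:900
  fit <- ann_fit(d$features[train, ], d$log2fc[train], seed = 7,
                 epochs = 500)
  pred <- predict(fit, d$features[-train, ], type = "log2fc")
  r <- cor(pred, d$log2fc[-train])
  expect_gt(r, 0.9)
})

test_that("model methods expose the standard fitted-model surface", {
  d <- gen_foldchange_dataset(80, seed = 41)
  fit <- ann_fit(d$features, d$log2fc, seed = 2, epochs = 100)
  expect_output(print(fit), "9-4-1 sigmoid network")
  expect_output(print(summary(fit)), "training Pearson r")
  expect_named(coef(fit), c("w_hidden", "b_hidden", "w_out", "b_out"))
  expect_equal(fitted(fit) + residuals(fit), d$log2fc)
  sim <- simulate(fit, nsim = 3, seed = 1)
  expect_identical(dim(sim), c(80L, 3L))
  expect_true(all(as.matrix(sim) < 0))
  expect_identical(simulate(fit, nsim = 2, seed = 5),
                   simulate(fit, nsim = 2, seed = 5))
  pdf(NULL)
  on.exit(dev.off())
  expect_silent(plot(fit))
})

test_that("JSON serialization round-trips predictions exactly", {
  d <- gen_foldchange_dataset(60, seed = 51)
  fit <- ann_fit(d$features, d$log2fc, seed = 2, epochs = 100)
  f <- withr::local_tempfile(fileext = ".json")
  write_ann(fit, f)
  back <- read_ann(f)
  expect_equal(predict(back, d$features), predict(fit, d$features),
               tolerance = 1e-12)
  expect_equal(back$target_scale, fit$target_scale)
})

test_that("cross-validation folds partition the data deterministically", {
  d <- gen_foldchange_dataset(120, seed = 61)
  cv <- cross_validate(d$features, d$log2fc, k = 10, seed = 3, epochs = 60)
  expect_length(cv$fold_rmse, 10L)
  expect_equal(cv$mean_rmse, mean(cv$fold_rmse))
  expect_true(all(cv$fold_rmse >= 0))
  # every record in exactly one test fold, folds near-equal
  expect_identical(sort(unique(cv$fold_id)), 1:10)
  expect_identical(unname(range(table(cv$fold_id))), c(12L, 12L))
  cv2 <- cross_validate(d$features, d$log2fc, k = 10, seed = 3, epochs = 60)
  expect_identical(cv$fold_rmse, cv2$fold_rmse)
  expect_error(cross_validate(d$features[1:5, ], d$log2fc[1:5], k = 10,
                              seed = 1), "at least k")
})

test_that("cross-validated error tracks the generator noise floor", {
  # near-noiseless planted model: held-out RMSE stays small
  d <- gen_foldchange_dataset(400, seed = 71, noise_sd = 0)
  cv <- cross_validate(d$features, d$log2fc, k = 10, seed = 3,
                       epochs = 1500)
  expect_lt(cv$mean_rmse, 0.1)

  # response independent of features: RMSE approaches sd(y)
  set.seed(72)
  x <- matrix(rpois(400 * 9, 1), 400, 9)
  y <- pmin(rnorm(400, -1, 0.4), -1e-6)
  cvn <- cross_validate(x, y, k = 10, seed = 3, epochs = 100)
  expect_lt(abs(cvn$mean_rmse - sd(y)) / sd(y), 0.25)
})

test_that("end-to-end prediction composes scanner, projection, network", {
  mir <- gen_mirna(91)
  d <- gen_foldchange_dataset(300, seed = 92)
  fit <- ann_fit(d$features, d$log2fc, seed = 3, epochs = 200)

  g0 <- gen_transcript(mir, NULL, seed = 93)
  p0 <- predict_repression(g0$transcript, mir, fit)
  expect_identical(nrow(p0$sites), 0L)
  expect_identical(sum(p0$counts), 0L)

  plan <- data.frame(region = "UTR3", mode = "MIR3P", kind = "6mer",
                     conserved = FALSE, count = 2L)
  g2 <- gen_transcript(mir, plan, seed = 94)
  p2 <- predict_repression(g2$transcript, mir, fit)
  expect_identical(nrow(p2$sites), 2L)
  # the planted type feeds feature 5; a positive-weight generator model
  # fitted on it should predict stronger repression than the empty case
  expect_gt(p2$score, p0$score)
  expect_identical(p2$predicted_log2fc, -p2$score * fit$target_scale)
  expect_identical(
    p2$score,
    predict_repression(g2$transcript, mir, fit)$score)  # determinism
})
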