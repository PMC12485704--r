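test_that("holdout split has the stated sizes, stratification and determinism", {
  sp <- holdout_split(1374, 0.2, seed = 1)
  expect_equal(length(sp$test), 275L)
  expect_equal(length(sp$train), 1099L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), 1:1374)

  sp2 <- holdout_split(10, 0.5, seed = 2)
  expect_equal(lengths(sp2), c(train = 5L, test = 5L))
  expect_identical(holdout_split(100, 0.3, seed = 9), holdout_split(100, 0.3, seed = 9))

  y <- rep(c(0, 1), c(60, 40))
  sps <- holdout_split(100, 0.2, seed = 3, stratify_labels = y)
  expect_equal(sum(y[sps$test]), 8)               # 40 * 0.2
  expect_error(holdout_split(10, 0.01), "empty")
})

test_that("stratified folds partition indices with balanced class counts", {
  y <- rep(c(0, 1), each = 50)
  folds <- stratified_kfold(y, k = 5, seed = 4)
  expect_equal(lengths(folds), rep(20L, 5))
  for (f in folds) expect_equal(sum(y[f]), 10)
  expect_setequal(unlist(folds), 1:100)
  expect_identical(folds, stratified_kfold(y, k = 5, seed = 4))
  expect_error(stratified_kfold(c(0, 0, 0, 1), k = 5), "stratification")
})

test_that("training reduces validation loss and respects patience", {
  d <- make_labeled_set(300, effect_size = 2, noise_sd = 0.3, seed = 6)
  sp <- holdout_split(300, 0.25, seed = 6, stratify_labels = d$y)
  m <- build_model(model_spec("cnn_attention", seed = 6))
  cfg <- train_config(seed = 6, max_epochs = 20)
  tr <- train_model(m, d$X[sp$train, ], d$y[sp$train],
                    d$X[sp$test, ], d$y[sp$test], cfg)
  h <- tr$history
  expect_lt(h$val_loss[nrow(h)], h$val_loss[1])
  # never trains more than `patience` epochs past the best epoch
  expect_lte(nrow(h) - tr$best_epoch, cfg$patience)
  # determinism: same seeds, same history
  tr2 <- train_model(build_model(model_spec("cnn_attention", seed = 6)),
                     d$X[sp$train, ], d$y[sp$train],
                     d$X[sp$test, ], d$y[sp$test], cfg)
  expect_identical(tr$history, tr2$history)
  expect_error(train_model(m, d$X[0, , drop = FALSE], numeric(0)), "empty")
})

test_that("cross-validation reports per-fold metrics and retrains the best fold", {
  d <- make_labeled_set(250, effect_size = 2, noise_sd = 0.5, seed = 8)
  cfg <- train_config(seed = 8, max_epochs = 6, n_folds = 5)
  out <- cross_validate_then_retrain(d$X, d$y, model_spec("cnn", seed = 8), cfg)
  expect_equal(nrow(out$cv), 5L)
  expect_true(all(out$cv$metric[out$selected_fold] >= out$cv$metric))
  expect_equal(out$selected_fold, which.max(out$cv$metric))
  expect_s3_class(out$model, "flex_model")
  # the retrained model ran for the selected fold's epoch budget
  expect_equal(nrow(out$model$history), out$cv$epochs[out$selected_fold])
})

test_that("AUC equals concordant-pair counting and is monotone-invariant", {
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.4, 0.35, 0.8)), 0.75)
  expect_equal(roc_auc(c(0, 0, 1, 1), c(0.1, 0.2, 0.7, 0.9)), 1)
  expect_equal(roc_auc(c(0, 1, 0, 1), rep(0.5, 4)), 0.5)
  set.seed(11)
  y <- rbinom(40, 1, 0.5); s <- rnorm(40)
  expect_equal(roc_auc(y, s), roc_auc(y, qlogis(plogis(s) * 0.98 + 0.01)))
  # brute-force pair-counting oracle
  pairs <- expand.grid(i = which(y == 1), j = which(y == 0))
  oracle <- mean(ifelse(s[pairs$i] > s[pairs$j], 1, ifelse(s[pairs$i] == s[pairs$j], 0.5, 0)))
  expect_equal(roc_auc(y, s), oracle)
  expect_error(roc_auc(rep(1, 4), runif(4)), "both classes")
})

test_that("bootstrap CI brackets the point AUC and is seeded", {
  set.seed(12)
  y <- rbinom(80, 1, 0.5); s <- y + rnorm(80)
  ci <- bootstrap_ci(y, s, n_boot = 300, seed = 5)
  a <- roc_auc(y, s)
  expect_lt(ci[1], a); expect_gt(ci[2], a)
  expect_identical(ci, bootstrap_ci(y, s, n_boot = 300, seed = 5))
  # calibration smoke: the CI contains the point estimate on most resampled sets
  hit <- 0L
  for (r in 1:20) {
    set.seed(100 + r)
    yy <- rbinom(60, 1, 0.5); ss <- yy * 0.8 + rnorm(60)
    cc <- bootstrap_ci(yy, ss, n_boot = 200, seed = r)
    if (roc_auc(yy, ss) >= cc[1] && roc_auc(yy, ss) <= cc[2]) hit <- hit + 1L
  }
  expect_gte(hit, 19L)
})

test_that("AP, max F1 and Youden match exhaustive threshold enumeration", {
  pm <- pr_metrics(c(0, 1), c(0.1, 0.9))
  expect_equal(pm$average_precision, 1)
  expect_equal(pm$max_f1, 1)
  yj <- youden(c(0, 1), c(0.1, 0.9))
  expect_equal(yj$j, 1)
  expect_gt(yj$threshold, 0.1); expect_lte(yj$threshold, 0.9)

  set.seed(13)
  y <- c(1, 0, 1, 1, 0, 0, 1, 0, 1, 0)
  s <- round(runif(10), 2)
  pm <- pr_metrics(y, s)
  yj <- youden(y, s)
  # exhaustive enumeration over all distinct thresholds
  ths <- sort(unique(s))
  stats_at <- t(vapply(ths, function(t) {
    tp <- sum(s >= t & y == 1); fp <- sum(s >= t & y == 0)
    prec <- tp / max(tp + fp, 1); rec <- tp / sum(y)
    c(prec = prec, rec = rec, tpr = rec, fpr = fp / sum(y == 0))
  }, numeric(4)))
  desc <- stats_at[order(ths, decreasing = TRUE), ]
  ap_oracle <- sum(diff(c(0, desc[, "rec"])) * desc[, "prec"])
  expect_equal(pm$average_precision, ap_oracle)
  f1 <- 2 * desc[, "prec"] * desc[, "rec"] / pmax(desc[, "prec"] + desc[, "rec"], 1e-12)
  expect_equal(pm$max_f1, max(f1))
  expect_equal(yj$j, max(stats_at[, "tpr"] - stats_at[, "fpr"]))
})

test_that("confusion rows are normalized and calibration bins are exact", {
  y <- c(0, 0, 1, 1)
  cc <- confusion_and_calibration(y, c(0.1, 0.2, 0.8, 0.9), threshold = 0.5)
  expect_equal(cc$confusion, diag(2), ignore_attr = TRUE)
  expect_equal(rowSums(cc$confusion), c("0" = 1, "1" = 1))
  expect_equal(sum(cc$calibration$count), 4L)
  # scores equal to empirical class frequencies calibrate perfectly
  y2 <- rep(c(0, 1, 1, 1), 5)
  cc2 <- confusion_and_calibration(y2, rep(0.75, 20), threshold = 0.5)
  expect_equal(cc2$calibration$observed_frequency, 0.75)
  expect_equal(cc2$calibration$mean_predicted, 0.75)
})

test_that("regression metrics match their closed forms", {
  y <- c(1, 2, 3, 4, 5)
  m <- regression_metrics(y, y)
  expect_equal(unlist(m), c(pearson_r = 1, r2 = 1, slope = 1, median_abs_error = 0))
  expect_equal(regression_metrics(y, 2 * y)$slope, 2)
  expect_equal(regression_metrics(y, 2 * y)$pearson_r, 1)
  set.seed(14)
  yt <- rnorm(60); yp <- 0.6 * yt + rnorm(60, sd = 0.4)
  m2 <- regression_metrics(yt, yp)
  expect_equal(m2$r2, cor(yt, yp)^2, tolerance = 1e-10)
  expect_equal(m2$slope, as.numeric(coef(lm(yp ~ yt))[2]), tolerance = 1e-10)
  expect_equal(m2$median_abs_error, median(abs(yp - yt)))
  expect_error(regression_metrics(y, rep(1, 5)), "zero variance")
})

test_that("metrics agree with an independent ROC implementation", {
  skip_if_not_installed("pROC")
  set.seed(15)
  y <- rbinom(50, 1, 0.5); s <- y + rnorm(50)
  ref <- as.numeric(suppressMessages(pROC::auc(pROC::roc(y, s, quiet = TRUE))))
  expect_equal(roc_auc(y, s), ref, tolerance = 1e-12)
})

test_that("pooled confusion equals the cluster-size-weighted sum of per-cluster ones", {
  set.seed(16)
  y <- rbinom(120, 1, 0.5); s <- plogis(y + rnorm(120))
  cl <- sample(1:3, 120, replace = TRUE)
  pooled <- confusion_and_calibration(y, s, 0.5)$counts
  summed <- Reduce(`+`, lapply(1:3, function(k)
    confusion_and_calibration(y[cl == k], s[cl == k], 0.5)$counts))
  expect_equal(pooled, summed)
})

test_that("integrated gradients satisfy completeness and linear exactness", {
  # exact on a linear model, even at few steps
  w <- rnorm(30); b <- 0.4
  lm_model <- gaussflex:::linear_model(w, b)
  x <- rnorm(30); base <- rnorm(30)
  ig <- integrated_gradients(lm_model, x, baseline = base, steps = 4)
  expect_equal(as.numeric(ig), w * (x - base), tolerance = 1e-12)

  # completeness on a trained nonlinear model
  d <- make_labeled_set(200, effect_size = 1.5, noise_sd = 0.5, seed = 17)
  fit <- flex_fit(d$X, d$y, "cnn_attention",
                  config = train_config(seed = 17, max_epochs = 6))
  xs <- d$X[1:8, ]
  ig <- integrated_gradients(fit$model, xs, steps = 256)
  pred <- as.numeric(predict(fit$model, xs))
  pred0 <- as.numeric(predict(fit$model, matrix(0, 1, 30)))
  expect_lt(max(abs(rowSums(ig) - (pred - pred0))) / max(abs(pred - pred0)), 0.01)

  svm <- build_model(model_spec("svm_rbf"))
  expect_error(integrated_gradients(svm, xs), "differentiable")
})
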