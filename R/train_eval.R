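# Training protocol: stratified splits, mini-batch Adam with early stopping,
# 5-fold cross-validation with best-fold retraining on the full pool.

#' Training configuration
#'
#' Defaults follow the study protocol: binary cross-entropy (classification)
#' or mean squared error (regression), Adam with learning rate 1e-3 and
#' weight decay 1e-4, batch size 32, early stopping with patience 7 within at
#' most 50 epochs, 5 cross-validation folds and a 20% holdout.
#'
#' @param loss `"bce"` or `"mse"`.
#' @param lr,weight_decay Adam hyperparameters.
#' @param batch_size mini-batch size.
#' @param max_epochs,patience early-stopping controls.
#' @param n_folds cross-validation folds.
#' @param holdout_fraction held-out test fraction.
#' @param seed integer seed for all run randomness.
#' @return A `train_config` list.
#' @export
train_config <- function(loss = c("bce", "mse"), lr = 1e-3, weight_decay = 1e-4,
                         batch_size = 32L, max_epochs = 50L, patience = 7L,
                         n_folds = 5L, holdout_fraction = 0.2, seed = 1L) {
  loss <- match.arg(loss)
  structure(list(loss = loss, lr = lr, weight_decay = weight_decay,
                 batch_size = as.integer(batch_size),
                 max_epochs = as.integer(max_epochs),
                 patience = as.integer(patience), n_folds = as.integer(n_folds),
                 holdout_fraction = holdout_fraction, seed = as.integer(seed)),
            class = "train_config")
}

#' Seeded train/test holdout split
#'
#' Test size is `round(fraction * n)`; with labels the split is stratified
#' (per-class rounding, remainder assigned to the largest class).
#'
#' @param n number of items.
#' @param fraction test fraction in (0, 1).
#' @param seed integer seed.
#' @param stratify_labels optional label vector of length n.
#' @return List with integer vectors `train` and `test`.
#' @export
holdout_split <- function(n, fraction, seed = 1L, stratify_labels = NULL) {
  if (fraction <= 0 || fraction >= 1) stop("fraction must be in (0, 1)", call. = FALSE)
  n_test <- round(fraction * n)
  if (n_test < 1L || n_test >= n) {
    stop("fraction yields an empty train or test side", call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  if (is.null(stratify_labels)) {
    test <- sort(sample.int(n, n_test))
  } else {
    stopifnot(length(stratify_labels) == n)
    classes <- split(seq_len(n), stratify_labels)
    take <- vapply(classes, function(ix) round(fraction * length(ix)), numeric(1))
    spare <- n_test - sum(take)
    if (spare != 0) {
      big <- which.max(lengths(classes))
      take[big] <- take[big] + spare
    }
    test <- sort(unlist(mapply(function(ix, k) sample(ix, k), classes, take,
                               SIMPLIFY = FALSE), use.names = FALSE))
  }
  list(train = setdiff(seq_len(n), test), test = test)
}

#' Stratified k-fold partition
#'
#' Shuffles within each class (seeded) and deals indices round-robin so every
#' fold's class proportions match the global ones as closely as counts allow.
#'
#' @param labels label vector.
#' @param k number of folds.
#' @param seed integer seed.
#' @return List of k disjoint validation-index vectors covering all indices.
#' @export
stratified_kfold <- function(labels, k = 5L, seed = 1L) {
  n <- length(labels)
  tab <- table(labels)
  if (any(tab < k)) {
    stop(sprintf("stratification error: class '%s' has fewer than %d members",
                 names(tab)[which.min(tab)], k), call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  folds <- vector("list", k)
  for (cl in split(seq_len(n), labels)) {
    cl <- sample(cl)
    assign_to <- rep_len(seq_len(k), length(cl))
    for (f in seq_len(k)) folds[[f]] <- c(folds[[f]], cl[assign_to == f])
  }
  lapply(folds, sort)
}

# rescale the gradient set so its global L2 norm is at most `max_norm`
# (stabilizes recurrent backpropagation in particular)
clip_global_norm <- function(grads, max_norm) {
  total <- sqrt(sum(unlist(rapply(grads, function(g) sum(g^2), how = "list"))))
  if (is.finite(total) && total > max_norm) {
    grads <- rapply(grads, function(g) g * (max_norm / total), how = "replace")
  }
  grads
}

loss_value <- function(loss, score, y) {
  if (loss == "bce") {
    p <- pmin(pmax(score, 1e-12), 1 - 1e-12)
    -mean(y * log(p) + (1 - y) * log(1 - p))
  } else {
    mean((score - y)^2)
  }
}

#' Train a neural flexibility model
#'
#' Mini-batch Adam with the configured loss, monitoring validation loss for
#' early stopping (stop after `patience` epochs without improvement, at most
#' `max_epochs`), restoring the best-validation weights. Fully deterministic
#' given the model seed and `config$seed`.
#'
#' @param model an initialized neural `flex_model` from [build_model()].
#' @param x_train,y_train,x_val,y_val training and validation partitions;
#'   `x_val` may be `NULL` to train for a fixed number of epochs.
#' @param config a [train_config].
#' @param epochs optional fixed epoch count overriding early stopping (used
#'   when retraining on the full pool).
#' @return The trained model, with `history` (data.frame of per-epoch train
#'   and validation loss) and `best_epoch` attached.
#' @export
train_model <- function(model, x_train, y_train, x_val = NULL, y_val = NULL,
                        config = train_config(), epochs = NULL) {
  if (model$spec$architecture == "svm_rbf") {
    model <- svm_fit(model, x_train, y_train)
    model$history <- data.frame(epoch = integer(), train_loss = numeric(),
                                val_loss = numeric())
    model$best_epoch <- NA_integer_
    return(model)
  }
  x_train <- as.matrix(x_train); y_train <- as.numeric(y_train)
  if (!nrow(x_train)) stop("empty training partition", call. = FALSE)
  has_val <- !is.null(x_val)
  if (has_val && !nrow(as.matrix(x_val))) stop("empty validation partition", call. = FALSE)
  n <- nrow(x_train)
  max_ep <- if (is.null(epochs)) config$max_epochs else as.integer(epochs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(config$seed + model$spec$seed)
  opt <- adam_init(model$params)
  best <- list(loss = Inf, params = model$params, epoch = 0L)
  hist_tr <- numeric(0); hist_val <- numeric(0)
  for (ep in seq_len(max_ep)) {
    ord <- sample.int(n)
    ep_loss <- 0; nb <- 0L
    for (start in seq(1L, n, by = config$batch_size)) {
      idx <- ord[start:min(start + config$batch_size - 1L, n)]
      xb <- x_train[idx, , drop = FALSE]; yb <- y_train[idx]
      fwd <- nn_forward(model, xb, keep_cache = TRUE)
      B <- length(idx)
      dz <- if (config$loss == "bce") (fwd$score - yb) / B else 2 * (fwd$z - yb) / B
      bk <- nn_backward(model, fwd, dz)
      grads <- clip_global_norm(bk$grads, 5)
      st <- adam_step(model$params, grads, opt, lr = config$lr,
                      weight_decay = config$weight_decay)
      model$params <- st$params
      opt <- st$state
      ep_loss <- ep_loss + loss_value(config$loss, fwd$score, yb)
      nb <- nb + 1L
    }
    hist_tr[ep] <- ep_loss / nb
    if (has_val) {
      vs <- nn_forward(model, as.matrix(x_val))$score
      vl <- loss_value(config$loss, vs, as.numeric(y_val))
      hist_val[ep] <- vl
      if (vl < best$loss - 1e-12) best <- list(loss = vl, params = model$params, epoch = ep)
      if (ep - best$epoch >= config$patience) break
    } else {
      hist_val[ep] <- NA_real_
    }
  }
  if (has_val) {
    model$params <- best$params
    model$best_epoch <- best$epoch
  } else {
    model$best_epoch <- max_ep
  }
  model$history <- data.frame(epoch = seq_along(hist_tr), train_loss = hist_tr,
                              val_loss = hist_val)
  model
}

#' Cross-validate, pick the best fold, retrain on the pool
#'
#' Runs stratified k-fold cross-validation on the training pool, selects the
#' fold with the highest validation accuracy (classification; ties to the
#' lowest fold index) or lowest validation loss (regression), re-initializes
#' with that fold's seed, and retrains on the whole pool for the selected
#' fold's early-stopped epoch count.
#'
#' @param x,y full training pool (holdout already removed).
#' @param spec a [model_spec].
#' @param config a [train_config].
#' @return List with the final `model`, `cv` (per-fold metric data.frame),
#'   `selected_fold` and the per-fold histories.
#' @export
cross_validate_then_retrain <- function(x, y, spec, config = train_config()) {
  x <- as.matrix(x); y <- as.numeric(y)
  classify <- spec$task == "classification"
  folds <- if (classify) {
    stratified_kfold(y, k = config$n_folds, seed = config$seed)
  } else {
    # stratify regression folds on above/below-median bins
    stratified_kfold(y > stats::median(y), k = config$n_folds, seed = config$seed)
  }
  fold_metric <- numeric(config$n_folds)
  fold_epochs <- integer(config$n_folds)
  histories <- vector("list", config$n_folds)
  for (f in seq_len(config$n_folds)) {
    val_idx <- folds[[f]]
    tr_idx <- setdiff(seq_len(nrow(x)), val_idx)
    fold_spec <- spec
    fold_spec$seed <- spec$seed + f
    m <- build_model(fold_spec)
    m <- train_model(m, x[tr_idx, , drop = FALSE], y[tr_idx],
                     x[val_idx, , drop = FALSE], y[val_idx], config)
    scores <- predict(m, x[val_idx, , drop = FALSE])
    fold_metric[f] <- if (classify) {
      mean(as.integer(scores > 0.5) == y[val_idx])
    } else {
      -loss_value("mse", scores, y[val_idx])
    }
    fold_epochs[f] <- if (is.na(m$best_epoch)) 1L else max(m$best_epoch, 1L)
    histories[[f]] <- m$history
  }
  sel <- which.max(fold_metric)           # ties resolve to the lowest index
  final_spec <- spec
  final_spec$seed <- spec$seed + sel
  final <- build_model(final_spec)
  final <- train_model(final, x, y, config = config, epochs = fold_epochs[sel])
  list(model = final,
       cv = data.frame(fold = seq_len(config$n_folds),
                       metric = fold_metric, epochs = fold_epochs),
       selected_fold = sel, histories = histories)
}
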