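#' Fit a protein-flexibility model to descriptor data
#'
#' The main modelling entry point: fits one of the four architectures
#' (attention-CNN, plain CNN, GRU recurrent network, SVM-RBF) to a
#' descriptor matrix and a flexibility target, either as a classifier
#' (binary flexible / non-flexible) or a regressor (continuous RMSF).
#' Neural architectures train with Adam, mini-batches and early stopping on
#' a validation split carved from the data; the SVM is fitted directly.
#'
#' @param x proteins x 30 descriptor matrix (unit-variance normalized; see
#'   [normalize_features()]).
#' @param y binary labels (0/1 or `flexible`/`non_flexible`) for
#'   classification, numeric RMSF values for regression.
#' @param architecture,task passed to [model_spec()].
#' @param config a [train_config]; its loss is matched to the task.
#' @param validation_fraction fraction of rows held out internally for early
#'   stopping (neural architectures).
#' @param seed integer seed for initialization and batching.
#' @return A `flex_fit` object with `model`, `history`, the training data
#'   dimensions and the call.
#' @examples
#' set.seed(1)
#' d <- make_labeled_set(200, effect_size = 1.5, noise_sd = 0.5, seed = 5)
#' fit <- flex_fit(d$X, d$y, architecture = "cnn_attention",
#'                 config = train_config(max_epochs = 3))
#' print(fit)
#' @export
flex_fit <- function(x, y, architecture = c("cnn_attention", "cnn", "rnn", "svm_rbf"),
                     task = c("classification", "regression"),
                     config = NULL, validation_fraction = 0.2, seed = 1L) {
  architecture <- match.arg(architecture)
  task <- match.arg(task)
  x <- as.matrix(x)
  if (is.character(y) || is.factor(y)) y <- as.integer(as.character(y) == "flexible")
  y <- as.numeric(y)
  stopifnot(nrow(x) == length(y))
  if (is.null(config)) {
    config <- train_config(loss = if (task == "classification") "bce" else "mse",
                           seed = seed)
  }
  spec <- model_spec(architecture, task, seed = seed)
  model <- build_model(spec)
  if (architecture == "svm_rbf") {
    model <- train_model(model, x, y, config = config)
  } else {
    strat <- if (task == "classification") y else y > stats::median(y)
    sp <- holdout_split(nrow(x), validation_fraction, seed = config$seed,
                        stratify_labels = strat)
    model <- train_model(model, x[sp$train, , drop = FALSE], y[sp$train],
                         x[sp$test, , drop = FALSE], y[sp$test], config)
  }
  structure(list(model = model, architecture = architecture, task = task,
                 history = model$history, n = nrow(x), config = config,
                 y = y, fitted_scores = predict(model, x),
                 call = match.call()),
            class = "flex_fit")
}

#' @export
print.flex_fit <- function(x, ...) {
  cat(sprintf("flex_fit: %s %s on %d proteins\n", x$architecture, x$task, x$n))
  if (nrow(x$history)) {
    cat(sprintf("  epochs run: %d, best epoch: %s\n", nrow(x$history),
                x$model$best_epoch))
  }
  invisible(x)
}

#' @export
summary.flex_fit <- function(object, ...) {
  cat(sprintf("%s %s model, %d training proteins\n", object$architecture,
              object$task, object$n))
  if (object$task == "classification") {
    auc <- roc_auc(object$y, object$fitted_scores)
    cat(sprintf("  in-sample AUC: %.3f\n", auc))
  } else {
    rm <- regression_metrics(object$y, object$fitted_scores)
    cat(sprintf("  in-sample r = %.3f, R^2 = %.3f, slope = %.3f, median |err| = %.3f\n",
                rm$pearson_r, rm$r2, rm$slope, rm$median_abs_error))
  }
  if (nrow(object$history)) {
    cat(sprintf("  final train loss %.4f; best validation loss %.4f (epoch %s)\n",
                utils::tail(object$history$train_loss, 1),
                min(object$history$val_loss, na.rm = TRUE),
                object$model$best_epoch))
  }
  invisible(object)
}

#' @export
predict.flex_fit <- function(object, newdata, ...) {
  predict(object$model, newdata, ...)
}

#' @export
residuals.flex_fit <- function(object, ...) {
  if (object$task != "regression") {
    stop("residuals are defined for regression fits", call. = FALSE)
  }
  object$y - object$fitted_scores
}

#' @export
plot.flex_fit <- function(x, ...) {
  h <- x$history
  if (!nrow(h)) {
    stop("no training history to plot (SVM fits train in one shot)", call. = FALSE)
  }
  ylim <- range(c(h$train_loss, h$val_loss), na.rm = TRUE)
  graphics::plot(h$epoch, h$train_loss, type = "l", xlab = "epoch",
                 ylab = "loss", ylim = ylim, ...)
  if (any(is.finite(h$val_loss))) {
    graphics::lines(h$epoch, h$val_loss, lty = 2)
    graphics::legend("topright", c("train", "validation"), lty = 1:2, bty = "n")
  }
  invisible(x)
}
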