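# The four flexibility model architectures: attention-CNN, plain CNN, GRU
# recurrent network and SVM with RBF kernel, each with a classification
# (sigmoid) or regression (identity) head.

#' Model specification
#'
#' Architecture and hyperparameters of a flexibility model. The CNNs use
#' four stacked 1D convolutional blocks with kernel size 3 and padding 1
#' (fixed), mapping 1 -> 32 -> 64 -> 64 -> 128 channels across the length-30
#' descriptor axis, so the positional axis is preserved and the aggregated
#' feature vector has 128 dimensions.
#'
#' @param architecture one of `"cnn_attention"`, `"cnn"`, `"rnn"`, `"svm_rbf"`.
#' @param task `"classification"` or `"regression"`.
#' @param conv_channels four conv output widths (last must be 128).
#' @param attention_dim width of the additive-attention projection.
#' @param rnn_hidden GRU hidden size.
#' @param svm_cost,svm_gamma SVM-RBF hyperparameters; `svm_gamma = "scale"`
#'   uses 1 / (30 * var(x)).
#' @param seed integer seed fixing parameter initialization.
#' @return A `model_spec` object.
#' @export
model_spec <- function(architecture = c("cnn_attention", "cnn", "rnn", "svm_rbf"),
                       task = c("classification", "regression"),
                       conv_channels = c(32L, 64L, 64L, 128L),
                       attention_dim = 64L, rnn_hidden = 64L,
                       svm_cost = 1, svm_gamma = "scale", seed = 1L) {
  architecture <- match.arg(architecture)
  task <- match.arg(task)
  conv_channels <- as.integer(conv_channels)
  if (length(conv_channels) != 4L || any(conv_channels < 1L)) {
    stop("conv_channels must be four positive counts", call. = FALSE)
  }
  if (conv_channels[4L] != 128L) {
    stop("the final convolutional width is fixed at 128", call. = FALSE)
  }
  structure(list(architecture = architecture, task = task,
                 conv_channels = conv_channels, kernel_size = 3L, padding = 1L,
                 attention_dim = as.integer(attention_dim),
                 rnn_hidden = as.integer(rnn_hidden),
                 svm_cost = svm_cost, svm_gamma = svm_gamma,
                 seed = as.integer(seed), input_length = 30L),
            class = "model_spec")
}

#' Build an initialized model from a specification
#'
#' Neural models receive seeded random parameters; the SVM handle stores the
#' specification and is fitted at training time.
#'
#' @param spec a [model_spec].
#' @return A `flex_model` handle.
#' @export
build_model <- function(spec) {
  stopifnot(inherits(spec, "model_spec"))
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  params <- switch(spec$architecture,
    cnn_attention = {
      ch <- c(1L, spec$conv_channels)
      list(conv = lapply(1:4, function(k) conv1d_init(ch[k], ch[k + 1L])),
           attn = attention_init(spec$conv_channels[4L], spec$attention_dim),
           fc = list(w = nn_unif(spec$conv_channels[4L], spec$conv_channels[4L]),
                     b = 0))
    },
    cnn = {
      ch <- c(1L, spec$conv_channels)
      list(conv = lapply(1:4, function(k) conv1d_init(ch[k], ch[k + 1L])),
           fc = list(w = nn_unif(spec$conv_channels[4L], spec$conv_channels[4L]),
                     b = 0))
    },
    rnn = list(gru = gru_init(spec$rnn_hidden),
               fc = list(w = nn_unif(spec$rnn_hidden, spec$rnn_hidden),
                         b = 0)),
    svm_rbf = NULL)
  structure(list(spec = spec, params = params, fitted = NULL),
            class = "flex_model")
}

#' @export
print.flex_model <- function(x, ...) {
  cat(sprintf("flex_model: %s (%s head)%s\n", x$spec$architecture, x$spec$task,
              if (is.null(x$fitted) && x$spec$architecture == "svm_rbf") ", unfitted" else ""))
  invisible(x)
}

# Full forward pass. Returns scores plus caches needed for backward, and the
# attention weights for attention models.
nn_forward <- function(model, X, keep_cache = FALSE) {
  spec <- model$spec
  B <- nrow(X); L <- spec$input_length
  if (ncol(X) != L) stop(sprintf("input must have %d columns", L), call. = FALSE)
  p <- model$params
  if (spec$architecture %in% c("cnn_attention", "cnn")) {
    maps <- conv1d_maps(B, L)
    H <- matrix(as.vector(t(X)), B * L, 1L)        # row r = (b-1)L + l
    caches <- vector("list", 4L)
    relu_masks <- vector("list", 4L)
    for (k in 1:4) {
      cv <- conv1d_forward(p$conv[[k]], H, maps)
      relu_masks[[k]] <- cv$out > 0
      H <- cv$out * relu_masks[[k]]
      caches[[k]] <- cv
    }
    if (spec$architecture == "cnn_attention") {
      at <- attention_forward(p$attn, H, B, L)
      context <- at$context
      alpha <- t(at$alpha)                          # B x L
    } else {
      at <- NULL
      context <- meanpool_forward(H, B, L)
      alpha <- NULL
    }
    z <- as.vector(context %*% p$fc$w) + p$fc$b
    score <- if (spec$task == "classification") sigmoid(z) else z
    out <- list(score = score, z = z, attention = alpha)
    if (keep_cache) out$cache <- list(maps = maps, conv = caches,
                                      relu = relu_masks, attn = at,
                                      context = context, H = H, B = B, L = L)
    out
  } else if (spec$architecture == "linear") {
    # linear scorer: used as a baseline and as the exactness reference for
    # path-integral attributions
    z <- as.vector(X %*% p$w) + p$b
    score <- if (spec$task == "classification") sigmoid(z) else z
    out <- list(score = score, z = z, attention = NULL)
    if (keep_cache) out$cache <- list(X = X, B = B, L = L)
    out
  } else if (spec$architecture == "rnn") {
    gr <- gru_forward(p$gru, X)
    z <- as.vector(gr$h %*% p$fc$w) + p$fc$b
    score <- if (spec$task == "classification") sigmoid(z) else z
    out <- list(score = score, z = z, attention = NULL)
    if (keep_cache) out$cache <- list(gru = gr, h = gr$h, X = X, B = B, L = L)
    out
  } else {
    stop("nn_forward does not apply to svm_rbf", call. = FALSE)
  }
}

# Backward pass from the gradient w.r.t. the pre-activation logit z.
# Returns parameter gradients (same shape as params) and the input gradient.
nn_backward <- function(model, fwd, dz) {
  spec <- model$spec
  p <- model$params
  cache <- fwd$cache
  B <- cache$B; L <- cache$L
  if (spec$architecture %in% c("cnn_attention", "cnn")) {
    dfc <- list(w = as.vector(crossprod(cache$context, dz)), b = sum(dz))
    dcontext <- outer(dz, p$fc$w)
    if (spec$architecture == "cnn_attention") {
      ab <- attention_backward(p$attn, cache$attn, dcontext, B, L)
      dH <- ab$dH
      dattn <- list(Wa = ab$dWa, ba = ab$dba, va = ab$dva)
    } else {
      dH <- dcontext[rep(seq_len(B), each = L), , drop = FALSE] / L
      dattn <- NULL
    }
    dconv <- vector("list", 4L)
    for (k in 4:1) {
      dH <- dH * cache$relu[[k]]
      cb <- conv1d_backward(p$conv[[k]], cache$conv[[k]], dH, cache$maps)
      dconv[[k]] <- list(W = cb$dW, b = cb$db)
      dH <- cb$dH
    }
    dX <- matrix(as.vector(dH), B, L, byrow = TRUE)
    grads <- if (is.null(dattn)) list(conv = dconv, fc = dfc) else
      list(conv = dconv, attn = dattn, fc = dfc)
    list(grads = grads, dX = dX)
  } else if (spec$architecture == "linear") {
    list(grads = list(w = as.vector(crossprod(cache$X, dz)), b = sum(dz)),
         dX = outer(dz, p$w))
  } else {
    dfc <- list(w = as.vector(crossprod(cache$h, dz)), b = sum(dz))
    dh <- outer(dz, p$fc$w)
    gb <- gru_backward(p$gru, cache$gru, dh, cache$X)
    list(grads = list(gru = gb$grads, fc = dfc), dX = gb$dX)
  }
}

#' Save / load a neural model checkpoint
#'
#' Checkpoints are plain JSON: the model specification plus every weight
#' array (with its dimensions), so they are portable and diffable. SVM
#' models store the support-vector machine via its own serialization and are
#' not supported here.
#'
#' @param model a neural `flex_model`.
#' @param path file path (`.json`).
#' @export
save_model <- function(model, path) {
  if (model$spec$architecture == "svm_rbf") {
    stop("SVM models are not checkpointable as JSON; refit from data", call. = FALSE)
  }
  enc <- function(p) {
    if (is.list(p)) lapply(p, enc)
    else list(dim = if (is.matrix(p)) dim(p) else length(p), values = as.numeric(p))
  }
  payload <- list(spec = unclass(model$spec), params = enc(model$params))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  raw <- jsonlite::fromJSON(path, simplifyVector = TRUE,
                            simplifyDataFrame = FALSE, simplifyMatrix = FALSE)
  spec <- raw$spec
  spec$conv_channels <- as.integer(spec$conv_channels)
  class(spec) <- "model_spec"
  dec <- function(p) {
    if (!is.null(p$values)) {
      v <- as.numeric(p$values)
      if (length(p$dim) == 2L) matrix(v, p$dim[1], p$dim[2]) else v
    } else lapply(p, dec)
  }
  structure(list(spec = spec, params = dec(raw$params), fitted = NULL),
            class = "flex_model")
}

# internal: a linear flex_model with explicit weights
linear_model <- function(w, b = 0, task = "regression") {
  structure(list(spec = list(architecture = "linear", task = task,
                             input_length = length(w), seed = 0L),
                 params = list(w = as.numeric(w), b = as.numeric(b)),
                 fitted = NULL),
            class = "flex_model")
}

#' Predict scores from a flexibility model
#'
#' Deterministic given fixed weights and independent of batch composition.
#' Classification scores are probabilities in (0, 1); regression scores are
#' unbounded reals.
#'
#' @param object a `flex_model`.
#' @param features proteins x 30 numeric matrix.
#' @param ... unused.
#' @return Numeric vector of scores, with attention weights (proteins x 30)
#'   as attribute `"attention"` for attention models.
#' @export
predict.flex_model <- function(object, features, ...) {
  features <- as.matrix(features)
  if (ncol(features) != object$spec$input_length) {
    stop(sprintf("feature matrix must have %d columns", object$spec$input_length),
         call. = FALSE)
  }
  if (object$spec$architecture == "svm_rbf") {
    if (is.null(object$fitted)) stop("SVM model has not been fitted", call. = FALSE)
    return(svm_scores(object, features))
  }
  fwd <- nn_forward(object, features)
  out <- fwd$score
  if (!is.null(fwd$attention)) attr(out, "attention") <- fwd$attention
  out
}

#' Attention weights over the 30 descriptor positions
#'
#' Returns the exact softmax weights used when aggregating the convolutional
#' features, one row per input.
#'
#' @param model an attention-architecture `flex_model`.
#' @param features proteins x 30 matrix.
#' @return proteins x 30 matrix of non-negative weights, rows summing to 1.
#' @export
attention_map <- function(model, features) {
  if (model$spec$architecture != "cnn_attention") {
    stop("attention weights are only defined for the cnn_attention architecture",
         call. = FALSE)
  }
  nn_forward(model, as.matrix(features))$attention
}

# --- SVM-RBF baseline (via e1071) ------------------------------------------

svm_fit <- function(model, X, y) {
  spec <- model$spec
  gamma <- if (identical(spec$svm_gamma, "scale")) {
    1 / (ncol(X) * stats::var(as.vector(X)))
  } else as.numeric(spec$svm_gamma)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(spec$seed)
  fit <- if (spec$task == "classification") {
    e1071::svm(x = X, y = factor(y, levels = c(0, 1)), kernel = "radial",
               cost = spec$svm_cost, gamma = gamma, probability = TRUE)
  } else {
    e1071::svm(x = X, y = as.numeric(y), kernel = "radial",
               cost = spec$svm_cost, gamma = gamma)
  }
  model$fitted <- fit
  model
}

svm_scores <- function(model, X) {
  if (model$spec$task == "classification") {
    pr <- stats::predict(model$fitted, X, probability = TRUE)
    p <- attr(pr, "probabilities")[, "1"]
    pmin(pmax(as.numeric(p), 1e-7), 1 - 1e-7)
  } else {
    as.numeric(stats::predict(model$fitted, X))
  }
}
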