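test_that("model specs validate their fixed architecture constraints", {
  spec <- model_spec("cnn_attention")
  expect_equal(spec$kernel_size, 3L)
  expect_equal(spec$padding, 1L)
  expect_equal(spec$conv_channels[4], 128L)
  expect_error(model_spec(conv_channels = c(32, 64, 64, 64)), "128")
  expect_error(model_spec(conv_channels = c(32, 64)), "four")
})

test_that("forward passes respect shapes, sigmoid bounds and attention simplex", {
  set.seed(1)
  X <- matrix(rnorm(5 * 30), 5, 30)
  for (arch in c("cnn_attention", "cnn", "rnn")) {
    m <- build_model(model_spec(arch, "classification", seed = 2))
    s <- predict(m, X)
    expect_length(as.numeric(s), 5L)
    expect_true(all(s > 0 & s < 1))
    mr <- build_model(model_spec(arch, "regression", seed = 2))
    sr <- predict(mr, X)
    expect_true(all(is.finite(sr)))
  }
  m <- build_model(model_spec("cnn_attention", seed = 2))
  a <- attention_map(m, X)
  expect_equal(dim(a), c(5L, 30L))
  expect_true(all(a >= 0))
  expect_equal(rowSums(a), rep(1, 5), tolerance = 1e-6)
  # aggregated feature vector is 128-dimensional
  fwd <- gaussflex:::nn_forward(m, X, keep_cache = TRUE)
  expect_equal(ncol(fwd$cache$context), 128L)
  # constant features give (near-)uniform attention by symmetry
  au <- attention_map(m, matrix(1, 2, 30))
  expect_lt(max(abs(au - 1 / 30)), 0.05)
  expect_error(attention_map(build_model(model_spec("cnn", seed = 1)), X),
               "attention")
  expect_error(predict(m, X[, 1:10]), "30")
})

test_that("seeding fixes weights and predictions are batch-independent", {
  X <- matrix(rnorm(6 * 30), 6, 30)
  m1 <- build_model(model_spec("cnn_attention", seed = 7))
  m2 <- build_model(model_spec("cnn_attention", seed = 7))
  expect_identical(m1$params, m2$params)
  s_batch <- as.numeric(predict(m1, X))
  s_single <- vapply(1:6, function(i) as.numeric(predict(m1, X[i, , drop = FALSE])),
                     numeric(1))
  expect_equal(s_batch, s_single, tolerance = 1e-6)
  # permuting rows permutes outputs
  perm <- c(3, 1, 6, 2, 5, 4)
  expect_equal(as.numeric(predict(m1, X[perm, ])), s_batch[perm])
})

test_that("analytic gradients match finite differences", {
  set.seed(9)
  X <- matrix(rnorm(4 * 30), 4, 30)
  y <- c(1, 0, 1, 0)
  for (arch in c("cnn_attention", "cnn", "rnn")) {
    m <- build_model(model_spec(arch, "classification", seed = 5))
    fwd <- gaussflex:::nn_forward(m, X, keep_cache = TRUE)
    dz <- (fwd$score - y) / 4
    bk <- gaussflex:::nn_backward(m, fwd, dz)
    lossfun <- function(model) {
      p <- pmin(pmax(gaussflex:::nn_forward(model, X)$score, 1e-12), 1 - 1e-12)
      -mean(y * log(p) + (1 - y) * log(1 - p))
    }
    modify <- function(params, path, i, d) {
      if (!length(path)) { params[i] <- params[i] + d; return(params) }
      params[[path[1]]] <- modify(params[[path[1]]], path[-1], i, d)
      params
    }
    eps <- 1e-6
    check <- function(pp, gg, path) {
      if (is.list(pp)) {
        for (j in seq_along(pp)) check(pp[[j]], gg[[j]], c(path, j))
      } else {
        for (i in sample(length(pp), min(2L, length(pp)))) {
          mp <- m; mp$params <- modify(m$params, path, i, eps)
          mn <- m; mn$params <- modify(m$params, path, i, -eps)
          num <- (lossfun(mp) - lossfun(mn)) / (2 * eps)
          expect_equal(gg[i], num, tolerance = 1e-4,
                       label = paste(arch, paste(path, collapse = "/")))
        }
      }
    }
    set.seed(2)
    check(m$params, bk$grads, integer(0))
  }
})

test_that("the SVM baseline fits, scores in (0,1), and refuses prediction unfitted", {
  d <- make_labeled_set(120, effect_size = 2, noise_sd = 0.3, seed = 4)
  m <- build_model(model_spec("svm_rbf", seed = 4))
  expect_error(predict(m, d$X), "not been fitted")
  m <- train_model(m, d$X, d$y)
  s <- predict(m, d$X)
  expect_true(all(s > 0 & s < 1))
  expect_gt(roc_auc(d$y, s), 0.8)
})

test_that("JSON checkpoints reproduce predictions exactly", {
  X <- matrix(rnorm(90), 3, 30)
  path <- withr::local_tempfile(fileext = ".json")
  for (arch in c("cnn_attention", "rnn")) {
    m <- build_model(model_spec(arch, "classification", seed = 5))
    save_model(m, path)
    expect_equal(as.numeric(predict(load_model(path), X)),
                 as.numeric(predict(m, X)))
  }
  expect_error(save_model(build_model(model_spec("svm_rbf")), path), "SVM")
})

test_that("a trained attention model concentrates weight on the planted component", {
  d <- make_labeled_set(400, informative_components = 7, effect_size = 2,
                        noise_sd = 0.3, seed = 13)
  fit <- flex_fit(d$X, d$y, "cnn_attention",
                  config = train_config(seed = 13, max_epochs = 25))
  att <- attention_map(fit$model, d$X)
  expect_lte(rank(-colMeans(att))[7], 3)
})
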