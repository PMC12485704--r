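test_that("unit-variance normalization fits, applies and warns on constants", {
  set.seed(1)
  X <- cbind(rnorm(50, sd = 2), rnorm(50, sd = 0.5), rep(3, 50))
  expect_warning(norm <- normalize_features(X), "zero-variance")
  expect_equal(apply(norm$X[, 1:2], 2, sd), c(1, 1), tolerance = 1e-10)
  expect_equal(norm$X[, 3], X[, 3])                   # constant column untouched
  # applying the fitted scaler to the fit data reproduces the fit output
  applied <- normalize_features(X, "apply", scaler = norm$scaler)
  expect_identical(applied$X, norm$X)
  expect_error(normalize_features(X, "apply"), "scaler")
  X[2, 1] <- NA
  expect_error(suppressWarnings(normalize_features(X)), "row 2")
})

test_that("PCA explains variance correctly and reconstructs at full rank", {
  # one direction of variation
  set.seed(2)
  t <- rnorm(40)
  X1 <- cbind(t, 2 * t, -t)
  p1 <- gi_pca(X1, k = 1)
  expect_equal(p1$explained_variance_ratio[1], 1, tolerance = 1e-10)

  # isotropic 2D Gaussian: two ratios near 1/2
  set.seed(3)
  X2 <- matrix(rnorm(40000), ncol = 2)
  p2 <- gi_pca(X2, k = 2)
  expect_lt(max(abs(p2$explained_variance_ratio - 0.5)), 0.02)
  # loadings orthonormal
  expect_equal(crossprod(p2$loadings), diag(2), tolerance = 1e-8, ignore_attr = TRUE)

  # exact reconstruction at k = rank
  set.seed(4)
  X3 <- matrix(rnorm(60), 20, 3)
  p3 <- gi_pca(X3, k = 3)
  rec <- sweep(p3$scores %*% t(p3$loadings), 2, p3$center, `+`)
  expect_equal(rec, X3, tolerance = 1e-8, ignore_attr = TRUE)

  expect_error(gi_pca(X3, k = 10), "exceeds")
  # ratios invariant to row permutation
  expect_equal(gi_pca(X3[sample(20), ], k = 3)$explained_variance_ratio,
               p3$explained_variance_ratio, tolerance = 1e-10)
})

test_that("k-means on PC scores recovers planted blobs deterministically", {
  set.seed(5)
  centers <- rbind(c(10, 0), c(-10, 0), c(0, 10), c(0, -10))
  truth <- rep(1:4, each = 25)
  S <- centers[truth, ] + matrix(rnorm(200, sd = 0.5), 100, 2)
  fake_pca <- list(scores = S)
  a1 <- cluster_scores(fake_pca, k = 4, seed = 1)
  a2 <- cluster_scores(fake_pca, k = 4, seed = 99)
  # perfect recovery: assignments refine the truth exactly
  expect_equal(length(unique(paste(truth, a1))), 4L)
  # restarts make the labeling seed-independent on separated blobs
  expect_equal(as.vector(a1), as.vector(a2))
  # k = 1 puts everything in cluster 1
  expect_true(all(cluster_scores(fake_pca, k = 1, seed = 1) == 1L))
  expect_error(cluster_scores(list(scores = S[1:2, ]), k = 4), "fewer rows")
})

test_that("majority secondary structure follows counts then the tie priority", {
  ann <- rep(c("helix", "sheet", "coil"), times = c(7, 2, 1))
  expect_equal(majority_secondary_structure(ann), "helix")
  expect_equal(majority_secondary_structure(rep("coil", 5)), "coil")
  expect_equal(majority_secondary_structure(rep(c("helix", "sheet"), each = 5)),
               "helix")
  expect_equal(majority_secondary_structure(rep(c("sheet", "coil"), each = 3)),
               "sheet")
  expect_error(majority_secondary_structure(character(0)), "empty")
})

test_that("cluster composition fractions are consistent and sum to one", {
  clusters <- stats::setNames(c(1, 1, 1, 1, 2, 2), paste0("p", 1:6))
  dominant <- stats::setNames(c("helix", "helix", "sheet", "coil", "helix", "helix"),
                              paste0("p", 1:6))
  labels <- stats::setNames(c("flexible", "flexible", "flexible", "non_flexible",
                              "non_flexible", "non_flexible"), paste0("p", 1:6))
  comp <- cluster_composition(clusters, dominant, labels,
                              rmsf = stats::setNames(1:6, paste0("p", 1:6)))
  expect_equal(comp$flexible_fraction, c(0.75, 0))
  expect_equal(comp$helix + comp$sheet + comp$coil, c(1, 1), tolerance = 1e-12)
  expect_equal(comp$helix[2], 1)
  expect_equal(comp$median_rmsf, c(2.5, 5.5))
  expect_error(cluster_composition(clusters, dominant[1:2], labels), "join error")
})
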