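test_that("segment writhe matches geometry ground truths", {
  # coplanar segments subtend zero solid angle
  expect_identical(segment_writhe(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(1, 1, 0)), 0)
  # segments sharing an endpoint
  expect_identical(segment_writhe(c(0, 0, 0), c(1, 0, 0), c(1, 0, 0), c(1, 1, 1)), 0)
  # chirality antisymmetry under z -> -z
  set.seed(4)
  for (i in 1:5) {
    p <- replicate(4, rnorm(3), simplify = FALSE)
    w <- segment_writhe(p[[1]], p[[2]], p[[3]], p[[4]])
    neg <- lapply(p, function(v) c(v[1], v[2], -v[3]))
    expect_equal(segment_writhe(neg[[1]], neg[[2]], neg[[3]], neg[[4]]), -w)
    expect_lte(abs(w), 1)
  }
  expect_error(segment_writhe(c(0, 0, 0), c(0, 0, 0), c(0, 1, 0), c(1, 1, 0)),
               "degenerate")
})

test_that("segment writhe agrees with the Monte-Carlo projection oracle", {
  set.seed(11)
  for (i in 1:3) {
    p <- replicate(4, rnorm(3), simplify = FALSE)
    w <- segment_writhe(p[[1]], p[[2]], p[[3]], p[[4]])
    mc <- mc_segment_writhe(p[[1]], p[[2]], p[[3]], p[[4]], m = 1e5, seed = 30 + i)
    expect_lt(abs(w - mc$mean), 3 * mc$se + 1e-12)
    if (abs(mc$mean) > 5 * mc$se) expect_equal(sign(w), sign(mc$mean))
  }
})

test_that("writhe matrix is symmetric, banded-zero and rigid-motion invariant", {
  tr <- make_backbone("coil", 10, seed = 3)
  W <- writhe_matrix(tr)
  expect_equal(W, t(W))
  expect_true(all(abs(W[abs(row(W) - col(W)) <= 1]) == 0))
  W2 <- writhe_matrix(rigid_motion(tr$coords, seed = 8))
  expect_equal(W, W2, tolerance = 1e-10)
  # planar curve: every entry zero
  expect_true(all(writhe_matrix(make_backbone("planar_zigzag", 12)) == 0))
})

test_that("the default registry has the documented structure", {
  reg <- default_registry()
  expect_equal(reg$size, 30L)
  nms <- registry_names(reg)
  expect_equal(nms[1:3], c("N", "I(1,2)", "I|1,2|"))
  orders <- vapply(reg$descriptors, `[[`, integer(1), "order")
  expect_equal(as.vector(table(orders)), c(1L, 2L, 12L, 15L))
  expect_false(anyDuplicated(nms) > 0)
})

test_that("invariant() matches brute-force enumeration on random matrices", {
  reg <- default_registry()
  for (s in 1:4) {
    W <- rand_writhe_like(12, seed = 100 + s)
    for (d in reg$descriptors) {
      if (d$order == 0L) next
      expect_equal(invariant(W, d$pattern), brute_invariant(W, d$pattern),
                   tolerance = 1e-10, label = d$name)
    }
  }
  # zero matrix: all patterns vanish
  Z <- matrix(0, 8, 8)
  expect_identical(invariant(Z, chord_pattern(list(c(1, 3), c(2, 4)))), 0)
  expect_error(invariant(matrix(0, 3, 3), chord_pattern(list(c(1, 2), c(3, 4), c(5, 6)))),
               "degenerate")
})

test_that("mirror reflection scales each invariant by (-1)^(non-abs chords)", {
  reg <- default_registry()
  W <- rand_writhe_like(10, seed = 77)
  for (d in reg$descriptors) {
    if (d$order == 0L) next
    k <- sum(!d$pattern$abs_flags)
    expect_equal(invariant(-W, d$pattern), (-1)^k * invariant(W, d$pattern),
                 tolerance = 1e-10, label = d$name)
  }
})

test_that("GI vectors respect rigid, scale and chirality symmetries", {
  reg <- default_registry()
  tr <- make_backbone("coil", 14, seed = 9)
  v <- compute_gi_vector(tr, reg)
  expect_length(v, 30L)
  expect_true(all(is.finite(v)))
  # rigid motion
  v_rigid <- compute_gi_vector(rigid_motion(tr$coords, 5), reg)
  expect_equal(v, v_rigid, tolerance = 1e-8)
  # uniform scale leaves all non-length descriptors unchanged
  v_scaled <- compute_gi_vector(tr$coords * 2, reg)
  expect_equal(v[-1], v_scaled[-1], tolerance = 1e-8)
  # mirror image: sign law per descriptor
  v_mirror <- compute_gi_vector(mirror_z(tr$coords), reg)
  for (i in seq_along(reg$descriptors)) {
    d <- reg$descriptors[[i]]
    k <- if (d$order == 0L) 0L else sum(!d$pattern$abs_flags)
    expect_equal(v_mirror[[i]], (-1)^k * v[[i]], tolerance = 1e-8, label = d$name)
  }
  # ACN dominates |writhe|
  expect_gte(v[["I|1,2|"]], abs(v[["I(1,2)"]]))
  expect_error(compute_gi_vector(make_backbone("helix", 7)$coords[1:6, ]), "degenerate")
})

test_that("right- and left-handed helices have opposite writhe", {
  vr <- compute_gi_vector(make_backbone("helix", 30))
  vl <- compute_gi_vector(make_backbone("helix", 30, handedness = "left"))
  expect_gt(abs(vr[["I(1,2)"]]), 0.1)
  expect_equal(vr[["I(1,2)"]], -vl[["I(1,2)"]], tolerance = 1e-8)
})

test_that("ACN projection estimate cross-validates the closed-form engine", {
  tr <- make_backbone("coil", 15, seed = 21)
  W <- writhe_matrix(tr)
  acn <- invariant(W, chord_pattern(list(c(1, 2)), abs_flags = TRUE))
  est <- acn_projection_estimate(tr, n_projections = 4e4, seed = 6)
  expect_lt(abs(est - acn), 3 * attr(est, "se"))
  expect_gte(as.numeric(est), 0)
  # zigzag has no self-crossings in any generic projection
  expect_equal(as.numeric(acn_projection_estimate(make_backbone("planar_zigzag", 10),
                                                  1e3, seed = 2)), 0)
})

test_that("registries round-trip through JSON", {
  reg <- default_registry()
  path <- withr::local_tempfile(fileext = ".json")
  write_registry(reg, path)
  back <- read_registry(path)
  expect_equal(registry_names(back), registry_names(reg))
  W <- rand_writhe_like(8, seed = 5)
  for (i in c(2, 7, 20)) {
    expect_equal(invariant(W, back$descriptors[[i]]$pattern),
                 invariant(W, reg$descriptors[[i]]$pattern))
  }
})
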