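test_that("Kabsch superposition recovers rigid motions exactly", {
  set.seed(2)
  ref <- matrix(rnorm(30), 10, 3)
  expect_equal(kabsch_superpose(rigid_motion(ref, 4), ref)$rmsd, 0, tolerance = 1e-8)
  expect_equal(kabsch_superpose(sweep(ref, 2, c(5, -3, 2), `+`), ref)$rmsd, 0,
               tolerance = 1e-10)
  # rotation is proper
  k <- kabsch_superpose(rigid_motion(ref, 9), ref)
  expect_equal(det(k$rotation), 1, tolerance = 1e-10)
  expect_error(kabsch_superpose(ref, ref[1:5, ]), "equal-sized")
})

test_that("Kabsch rmsd matches a brute-force optimizer on noisy points", {
  set.seed(10)
  ref <- matrix(rnorm(12), 4, 3)
  mob <- rigid_motion(ref, 3) + matrix(rnorm(12, sd = 0.1), 4, 3)
  got <- kabsch_superpose(mob, ref)$rmsd
  # numeric optimization over an axis-angle + translation parameterization
  obj <- function(par) {
    ax <- par[1:3]; th <- sqrt(sum(ax^2))
    R <- diag(3)
    if (th > 1e-12) {
      k <- ax / th
      K <- matrix(c(0, -k[3], k[2], k[3], 0, -k[1], -k[2], k[1], 0), 3, 3, byrow = TRUE)
      R <- diag(3) + sin(th) * K + (1 - cos(th)) * K %*% K
    }
    moved <- sweep(mob %*% t(R), 2, par[4:6], `+`)
    sqrt(mean(rowSums((moved - ref)^2)))
  }
  best <- Inf
  for (s in 1:8) {
    set.seed(s)
    o <- stats::optim(c(rnorm(3), rnorm(3)), obj, method = "BFGS",
                      control = list(maxit = 500, reltol = 1e-14))
    best <- min(best, o$value)
  }
  expect_equal(got, best, tolerance = 1e-6)
  expect_lte(got, best + 1e-8)   # Kabsch is the true minimum
})

test_that("RMSF vanishes for rigid ensembles and recovers isotropic noise", {
  h <- make_backbone("helix", 40)
  rigid <- make_trajectory(h, 0, n_frames = 20, n_replicates = 1, seed = 1)
  expect_lt(max(rmsf_profile(rigid$replicates[[1]])), 1e-8)

  tj <- make_trajectory(h, 0.5, n_frames = 400, n_replicates = 1, seed = 2)
  pr <- rmsf_profile(tj$replicates[[1]])
  expect_equal(mean(pr), 0.5 * sqrt(3), tolerance = 0.05)

  # doubling sigma doubles RMSF within sampling error
  tj2 <- make_trajectory(h, 1.0, n_frames = 400, n_replicates = 1, seed = 2)
  expect_equal(mean(rmsf_profile(tj2$replicates[[1]])) / mean(pr), 2, tolerance = 0.05)
})

test_that("RMSF is invariant to a global rigid motion of every frame", {
  h <- make_backbone("helix", 20)
  tj <- make_trajectory(h, 0.4, n_frames = 50, n_replicates = 1, seed = 6)
  pr1 <- rmsf_profile(tj$replicates[[1]])
  set.seed(42)
  q <- qr.Q(qr(matrix(rnorm(9), 3, 3))); if (det(q) < 0) q[, 1] <- -q[, 1]
  moved <- tj$replicates[[1]]
  for (f in seq_len(dim(moved)[1])) {
    moved[f, , ] <- sweep(moved[f, , ] %*% q, 2, c(3, -7, 11), `+`)
  }
  expect_equal(rmsf_profile(moved), pr1, tolerance = 1e-8)
})

test_that("replicate aggregation is the stated double mean", {
  expect_equal(aggregate_rmsf(list(c(1, 1, 1), c(1, 1, 1), c(1, 1, 1))), 1)
  expect_equal(aggregate_rmsf(list(c(0, 0), c(2, 2))), 1)
  expect_equal(aggregate_rmsf(list(c(1, 3), c(2, 4))), 2.5)
  expect_error(aggregate_rmsf(list(c(1, 2), c(1, 2, 3))), "mismatch")
  # k identical replicates equal the single-replicate value exactly
  p <- c(0.2, 0.9, 0.4)
  expect_identical(aggregate_rmsf(list(p, p, p)), aggregate_rmsf(list(p)))
})

test_that("flexibility labels follow the strict-above-mean rule", {
  lab <- flexibility_labels(c(a = 1, b = 3))
  expect_equal(lab$label, c("non_flexible", "flexible"))
  # ties at the threshold are non-flexible
  lab2 <- flexibility_labels(c(a = 2, b = 2))
  expect_true(all(lab2$label == "non_flexible"))
  lab3 <- flexibility_labels(c(a = 0.3, b = 0.8), threshold = 0)
  expect_true(all(lab3$label == "flexible"))
  expect_error(flexibility_labels(numeric(0)), "degenerate")
  expect_error(flexibility_labels(c(a = 1)), "at least 2")
  # counts always partition the set
  set.seed(3)
  v <- stats::setNames(runif(20), paste0("p", 1:20))
  lab4 <- flexibility_labels(v)
  expect_equal(sum(lab4$label == "flexible") + sum(lab4$label == "non_flexible"), 20L)
  expect_gte(sum(lab4$label == "non_flexible"), 1L)
})

test_that("per-residue RMSF recovers a planted sigma profile shape", {
  h <- make_backbone("helix", 60)
  prof <- c(rep(0.2, 20), rep(1.0, 20), rep(0.2, 20))
  tj <- make_trajectory(h, prof, n_frames = 600, n_replicates = 2, seed = 12)
  er <- ensemble_rmsf(tj)
  expect_gt(stats::cor(er$mean_profile, prof), 0.99)
  expect_length(er$profiles, 2L)
  expect_equal(er$scalar, mean(er$mean_profile))
})
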