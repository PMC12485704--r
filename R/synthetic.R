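# Synthetic test-data generators: parametric backbones, noisy trajectory
# ensembles with known per-residue fluctuation, and labelled descriptor sets
# with planted signal. These define the study conditions for every test in
# the package; no downloads are needed anywhere.

#' Generate a parametric C-alpha backbone
#'
#' Backbone kinds: `helix` (ideal C-alpha helix on a cylinder; rise 1.5 A,
#' turn 100 degrees, radius 2.3 A by default, uniformly rescaled so the
#' C-alpha step equals `bond_length`), `strand` (near-linear pleated zigzag
#' with a slight out-of-plane twist), `hairpin` (two antiparallel strands
#' joined by a semicircular turn), `coil` (seeded self-avoiding random walk,
#' fixed 3.8 A step, minimum non-bonded distance 3.0 A) and `planar_zigzag`
#' (lies exactly in z = 0; every Gauss integral vanishes on it).
#'
#' @param kind one of `"helix"`, `"strand"`, `"hairpin"`, `"coil"`,
#'   `"planar_zigzag"`.
#' @param n_residues number of residues (>= 7).
#' @param handedness `"right"` or `"left"`; left-handed output is the exact
#'   mirror image (z negated) of the right-handed one.
#' @param bond_length consecutive C-alpha distance, Angstrom.
#' @param rise,turn_deg,radius helix geometry before rescaling.
#' @param seed RNG seed (coil only).
#' @param chain_id chain identifier for the returned trace.
#' @return A [ca_trace].
#' @examples
#' helix <- make_backbone("helix", 50)
#' range(sqrt(rowSums(diff(helix$coords)^2)))
#' @export
make_backbone <- function(kind = c("helix", "strand", "hairpin", "coil", "planar_zigzag"),
                          n_residues = 50L, handedness = c("right", "left"),
                          bond_length = 3.8, rise = 1.5, turn_deg = 100,
                          radius = 2.3, seed = 1L, chain_id = "A") {
  kind <- match.arg(kind)
  handedness <- match.arg(handedness)
  n <- as.integer(n_residues)
  if (n < 7L) stop("n_residues must be >= 7", call. = FALSE)
  if (bond_length <= 0) stop("bond_length must be positive", call. = FALSE)
  coords <- switch(kind,
    helix = {
      theta <- (seq_len(n) - 1L) * turn_deg * pi / 180
      xyz <- cbind(radius * cos(theta), radius * sin(theta), (seq_len(n) - 1L) * rise)
      step <- sqrt(sum((xyz[2L, ] - xyz[1L, ])^2))
      xyz * (bond_length / step)
    },
    strand = {
      # pleat in y, slight alternating twist in z; step renormalized exactly
      dy <- 0.95; dz <- 0.4
      dx <- sqrt(bond_length^2 - dy^2 - dz^2)
      steps <- cbind(dx, dy * (-1)^(seq_len(n - 1L)), dz * (-1)^ceiling(seq_len(n - 1L) / 2))
      apply(rbind(0, steps), 2, cumsum)
    },
    planar_zigzag = {
      dy <- 1.4
      dx <- sqrt(bond_length^2 - dy^2)
      steps <- cbind(dx, dy * (-1)^(seq_len(n - 1L)), 0)
      apply(rbind(0, steps), 2, cumsum)
    },
    hairpin = make_hairpin(n, bond_length),
    coil = make_coil(n, bond_length, seed))
  if (handedness == "left") coords[, 3] <- -coords[, 3]
  ca_trace(coords, chain_id = chain_id)
}

make_hairpin <- function(n, bond_length) {
  # U-shaped curve: arm out along +x, semicircular turn, arm back along -x,
  # with an alternating z pleat so the curve is not exactly planar.
  n_turn <- 4L
  n1 <- (n - n_turn) %/% 2L
  n2 <- n - n_turn - n1
  R <- 2.4                                     # half the strand separation
  arm1 <- cbind((seq_len(n1) - 1L) * bond_length, 0, 0)
  centre <- c(arm1[n1, 1], R, 0)
  ang <- -pi / 2 + seq_len(n_turn) * pi / (n_turn + 1L)
  turn <- cbind(centre[1] + R * cos(ang), centre[2] + R * sin(ang), 0)
  arm2 <- cbind(arm1[n1, 1] - (seq_len(n2)) * bond_length, 2 * R, 0)
  pts <- rbind(arm1, turn, arm2)
  pts[, 3] <- 0.8 * (-1)^(seq_len(nrow(pts)))
  pts
}

make_coil <- function(n, bond_length, seed) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  max_retry <- 1e4L
  pts <- matrix(0, n, 3)
  pts[2L, ] <- c(bond_length, 0, 0)
  for (i in 3:n) {
    ok <- FALSE
    for (try in seq_len(max_retry)) {
      d <- stats::rnorm(3)
      d <- d / sqrt(sum(d^2))
      cand <- pts[i - 1L, ] + bond_length * d
      prev <- pts[seq_len(i - 2L), , drop = FALSE]
      if (min(sqrt(rowSums((prev - matrix(cand, nrow(prev), 3, byrow = TRUE))^2))) >= 3.0) {
        pts[i, ] <- cand
        ok <- TRUE
        break
      }
    }
    if (!ok) stop("self-avoiding walk failed after 10^4 retries", call. = FALSE)
  }
  pts
}

#' Generate a noisy multi-replicate trajectory ensemble
#'
#' Frames are the reference trace plus i.i.d. Gaussian noise per residue and
#' coordinate (standard deviation from `sigma_profile`), composed with a
#' random rigid motion per frame so that RMSF computation must superpose.
#' Replicate r uses seed `seed + r - 1`, making the whole ensemble a
#' deterministic function of `seed`.
#'
#' @param reference a [ca_trace].
#' @param sigma_profile per-residue noise sd, Angstrom (recycled if scalar).
#' @param n_frames frames per replicate (>= 2).
#' @param n_replicates number of replicates.
#' @param seed integer seed.
#' @return A `trajectory_ensemble`: list of replicates, each an array
#'   (n_frames x n_residues x 3).
#' @export
make_trajectory <- function(reference, sigma_profile, n_frames = 100L,
                            n_replicates = 3L, seed = 1L) {
  coords <- trace_coords(reference)
  n <- nrow(coords)
  sigma_profile <- rep_len(as.numeric(sigma_profile), n)
  if (any(sigma_profile < 0)) stop("sigma_profile must be non-negative", call. = FALSE)
  if (n_frames < 2L) stop("need at least 2 frames per replicate", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  reps <- lapply(seq_len(n_replicates), function(r) {
    set.seed(seed + r - 1L)
    frames <- array(0, dim = c(n_frames, n, 3))
    for (f in seq_len(n_frames)) {
      noise <- matrix(stats::rnorm(3 * n, sd = rep(sigma_profile, 3)), n, 3)
      rot <- random_rotation()
      shift <- stats::runif(3, -5, 5)
      frames[f, , ] <- sweep((coords + noise) %*% rot, 2, -shift)
    }
    frames
  })
  structure(list(replicates = reps, n_residues = n,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "trajectory_ensemble")
}

random_rotation <- function() {
  # QR of a Gaussian matrix, corrected to a proper rotation
  q <- qr.Q(qr(matrix(stats::rnorm(9), 3, 3)))
  if (det(q) < 0) q[, 1] <- -q[, 1]
  q
}

#' Generate a labelled descriptor dataset with planted signal
#'
#' Emulates the unit-variance, uncentered descriptor tables the flexibility
#' models consume: each component has unit-variance Gaussian fluctuation
#' around a fixed component-specific offset (`component_means`), mirroring
#' how real Gauss-integral descriptors are identifiable by their
#' characteristic magnitudes after variance scaling. The latent signal is
#' `s = effect_size * sum(X[, informative] - mean[informative])` and the
#' target adds Gaussian noise: classification labels are `y = 1` iff
#' `s + noise > 0`, regression targets are `y = s + noise`. The achievable
#' (Bayes) AUC or R-squared is computed in closed form from `effect_size`,
#' the number of informative components and `noise_sd`, and returned
#' alongside the data.
#'
#' @param n number of rows.
#' @param informative_components integer indices in 1..30.
#' @param effect_size per-component effect.
#' @param noise_sd sd of the additive noise.
#' @param task `"classification"` or `"regression"`.
#' @param component_means length-30 vector of fixed component offsets;
#'   `NULL` gives the package default (a fixed spread over \[-5, 5\]); use
#'   `rep(0, 30)` for fully exchangeable columns.
#' @param seed integer seed.
#' @return A `synthetic_labeled_set`: list with `X` (n x 30), `y`,
#'   `bayes_auc` or `r2_true`, and the generator parameters.
#' @export
make_labeled_set <- function(n, informative_components = c(7L, 15L, 23L),
                             effect_size = 1, noise_sd = 1,
                             task = c("classification", "regression"),
                             component_means = NULL, seed = 1L) {
  task <- match.arg(task)
  informative_components <- as.integer(informative_components)
  if (effect_size > 0 && !length(informative_components)) {
    stop("informative_components must be non-empty when effect_size > 0", call. = FALSE)
  }
  if (length(informative_components) &&
      (min(informative_components) < 1L || max(informative_components) > 30L)) {
    stop("informative_components must lie in 1..30", call. = FALSE)
  }
  if (is.null(component_means)) component_means <- default_component_means()
  component_means <- rep_len(as.numeric(component_means), 30L)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  X <- matrix(stats::rnorm(n * 30L), n, 30L)
  X <- sweep(X, 2, component_means, `+`)
  colnames(X) <- registry_names(default_registry())
  s <- if (length(informative_components)) {
    centred <- sweep(X[, informative_components, drop = FALSE], 2,
                     component_means[informative_components])
    effect_size * rowSums(centred)
  } else rep(0, n)
  eps <- stats::rnorm(n, sd = noise_sd)
  tau <- effect_size * sqrt(length(informative_components))
  out <- list(X = X, informative_components = informative_components,
              effect_size = effect_size, noise_sd = noise_sd,
              component_means = component_means,
              task = task, seed = as.integer(seed))
  if (task == "classification") {
    out$y <- as.integer(s + eps > 0)
    out$bayes_auc <- planted_bayes_auc(effect_size, length(informative_components), noise_sd)
  } else {
    out$y <- s + eps
    out$r2_true <- if (tau == 0 && noise_sd == 0) NA_real_ else tau^2 / (tau^2 + noise_sd^2)
  }
  structure(out, class = "synthetic_labeled_set")
}

# Fixed per-component offsets: a spread over [-5, 5] in a fixed scrambled
# order, so neighbouring positions differ in characteristic magnitude the
# way real descriptor components do.
default_component_means <- function() {
  perm <- c(17L, 5L, 1L, 25L, 10L, 4L, 18L, 30L, 15L, 7L, 27L, 29L, 14L, 22L,
            3L, 9L, 23L, 11L, 20L, 19L, 13L, 12L, 2L, 24L, 16L, 8L, 28L, 26L,
            6L, 21L)
  seq(-5, 5, length.out = 30L)[perm]
}

#' Bayes AUC of the planted classification model
#'
#' With latent signal `s ~ N(0, tau^2)` (`tau = effect_size * sqrt(k)`) and
#' labels `1{s + eps > 0}`, `eps ~ N(0, noise_sd^2)`, the optimal score is
#' `s` itself. Writing `rho = tau / sqrt(tau^2 + noise_sd^2)` for the
#' correlation between score and latent target, the concordance probability
#' reduces to a trivariate-normal orthant probability with the exact value
#' `AUC = 1/2 + (2/pi) * asin(rho / sqrt(2))`.
#'
#' @param effect_size per-component effect.
#' @param n_informative number of informative components k.
#' @param noise_sd additive noise sd.
#' @return The Bayes AUC in \[0.5, 1\].
#' @export
planted_bayes_auc <- function(effect_size, n_informative, noise_sd) {
  tau <- effect_size * sqrt(n_informative)
  if (tau == 0) return(0.5)
  rho <- tau / sqrt(tau^2 + noise_sd^2)
  0.5 + (2 / pi) * asin(rho / sqrt(2))
}

#' Noise level achieving a target Bayes AUC
#'
#' Exact inverse of [planted_bayes_auc()] in `noise_sd`.
#'
#' @param target_auc desired Bayes AUC in (0.5, 1).
#' @param effect_size,n_informative planted-signal parameters.
#' @return The `noise_sd` giving the target AUC.
#' @export
noise_for_bayes_auc <- function(target_auc, effect_size = 1, n_informative = 3L) {
  stopifnot(target_auc > 0.5, target_auc < 1)
  tau <- effect_size * sqrt(n_informative)
  rho <- sqrt(2) * sin((target_auc - 0.5) * pi / 2)
  tau * sqrt(1 / rho^2 - 1)
}

#' Noise level achieving a target latent R-squared
#'
#' @param target_r2 desired true R-squared in (0, 1).
#' @param effect_size,n_informative planted-signal parameters.
#' @return The `noise_sd` with `tau^2 / (tau^2 + noise_sd^2) = target_r2`.
#' @export
noise_for_r2 <- function(target_r2, effect_size = 1, n_informative = 3L) {
  stopifnot(target_r2 > 0, target_r2 < 1)
  tau <- effect_size * sqrt(n_informative)
  tau * sqrt((1 - target_r2) / target_r2)
}
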