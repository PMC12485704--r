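# RMSF from coordinate ensembles: optimal superposition, per-residue
# fluctuation profiles, replicate aggregation, and binary flexibility labels.

#' Least-squares rigid superposition (Kabsch)
#'
#' Optimal proper rotation and translation of `mobile` onto `reference`,
#' computed from the SVD of the covariance matrix with the determinant
#' correction that excludes reflections.
#'
#' @param mobile,reference n x 3 coordinate matrices, n >= 3.
#' @return List with `aligned` (transformed mobile coordinates), `rmsd`
#'   (minimized value, Angstrom), `rotation` and `translation`.
#' @export
kabsch_superpose <- function(mobile, reference) {
  mobile <- as.matrix(mobile); reference <- as.matrix(reference)
  if (!all(dim(mobile) == dim(reference)) || ncol(mobile) != 3L) {
    stop("mobile and reference must be equal-sized n x 3 matrices", call. = FALSE)
  }
  if (nrow(mobile) < 3L) stop("need at least 3 points", call. = FALSE)
  cm <- colMeans(mobile); cr <- colMeans(reference)
  A <- sweep(mobile, 2, cm); B <- sweep(reference, 2, cr)
  H <- t(A) %*% B
  sv <- svd(H)
  if (min(sv$d) < 1e-10 * max(sv$d, 1e-300)) {
    warning("near-degenerate point configuration; superposition may be ill-conditioned",
            call. = FALSE)
  }
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  aligned <- sweep(A %*% t(R), 2, -cr)
  list(aligned = aligned,
       rmsd = sqrt(mean(rowSums((aligned - reference)^2))),
       rotation = R, translation = cr - as.vector(R %*% cm))
}

#' Per-residue RMSF of one replicate
#'
#' Frames are superposed onto an iteratively refined mean structure (align
#' all frames to the running mean, recompute the mean; stop when the mean
#' shifts by less than 1e-6 A or after 10 iterations), then
#' `RMSF_i = sqrt(mean_frames |x_i - mean_i|^2)`.
#'
#' @param frames array (n_frames x n_residues x 3) or list of n x 3 matrices.
#' @return Numeric vector of per-residue RMSF values, Angstrom.
#' @export
rmsf_profile <- function(frames) {
  frames <- as_frame_list(frames)
  nf <- length(frames)
  if (nf < 2L) stop("need at least 2 frames", call. = FALSE)
  n <- nrow(frames[[1L]])
  for (f in frames) {
    if (!all(dim(f) == c(n, 3L))) stop("frame shape mismatch", call. = FALSE)
  }
  mean_str <- frames[[1L]]
  for (iter in seq_len(10L)) {
    aligned <- lapply(frames, function(f) kabsch_superpose(f, mean_str)$aligned)
    new_mean <- Reduce(`+`, aligned) / nf
    shift <- sqrt(mean(rowSums((new_mean - mean_str)^2)))
    mean_str <- new_mean
    if (shift < 1e-6) break
  }
  aligned <- lapply(frames, function(f) kabsch_superpose(f, mean_str)$aligned)
  mean_str <- Reduce(`+`, aligned) / nf
  sq <- Reduce(`+`, lapply(aligned, function(a) rowSums((a - mean_str)^2))) / nf
  sqrt(sq)
}

as_frame_list <- function(frames) {
  if (is.list(frames)) return(lapply(frames, as.matrix))
  if (is.array(frames) && length(dim(frames)) == 3L) {
    return(lapply(seq_len(dim(frames)[1L]), function(f) frames[f, , ]))
  }
  stop("frames must be a list of n x 3 matrices or an (n_frames x n x 3) array",
       call. = FALSE)
}

#' Aggregate replicate RMSF profiles to one scalar per protein
#'
#' Per-residue mean across replicates, then arithmetic mean over residues.
#'
#' @param profiles list of equal-length numeric RMSF profiles.
#' @return A single non-negative scalar, Angstrom.
#' @export
aggregate_rmsf <- function(profiles) {
  if (!is.list(profiles)) profiles <- list(profiles)
  if (!length(profiles)) stop("degenerate input: no profiles", call. = FALSE)
  n <- length(profiles[[1L]])
  for (p in profiles) {
    if (length(p) != n) stop("profile length mismatch", call. = FALSE)
  }
  mean(Reduce(`+`, profiles) / length(profiles))
}

#' RMSF of a trajectory ensemble
#'
#' Convenience wrapper: per-replicate [rmsf_profile()], replicate-averaged
#' profile, and the per-protein scalar from [aggregate_rmsf()].
#'
#' @param ensemble a `trajectory_ensemble` from [make_trajectory()] or a list
#'   of replicates (each frames x residues x 3).
#' @return List with `profiles` (per replicate), `mean_profile` and `scalar`.
#' @export
ensemble_rmsf <- function(ensemble) {
  reps <- if (inherits(ensemble, "trajectory_ensemble")) ensemble$replicates else ensemble
  profiles <- lapply(reps, rmsf_profile)
  mean_profile <- Reduce(`+`, profiles) / length(profiles)
  list(profiles = profiles, mean_profile = mean_profile,
       scalar = aggregate_rmsf(profiles))
}

#' Binary flexibility labels from per-protein RMSF scalars
#'
#' A protein is labelled `flexible` iff its RMSF scalar exceeds the
#' threshold; a value exactly at the threshold is `non_flexible` ("above"
#' is strict). The default threshold is the dataset-wide mean.
#'
#' @param values named numeric vector of per-protein RMSF scalars.
#' @param threshold `"dataset_mean"` or an explicit numeric threshold.
#' @return data.frame with `protein_id`, `rmsf_scalar`, `label` and the
#'   threshold used as attribute `"threshold"`.
#' @export
flexibility_labels <- function(values, threshold = "dataset_mean") {
  if (!length(values)) stop("degenerate input: no RMSF values", call. = FALSE)
  if (identical(threshold, "dataset_mean")) {
    if (length(values) < 2L) {
      stop("dataset_mean threshold needs at least 2 proteins", call. = FALSE)
    }
    thr <- mean(values)
  } else {
    thr <- as.numeric(threshold)
  }
  ids <- names(values)
  if (is.null(ids)) ids <- as.character(seq_along(values))
  out <- data.frame(protein_id = ids,
                    rmsf_scalar = as.numeric(values),
                    label = ifelse(values > thr, "flexible", "non_flexible"),
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- thr
  out
}
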