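# Descriptor-matrix statistics: unit-variance normalization, PCA, k-means
# clustering in PC space, and cluster composition summaries.

#' Unit-variance feature normalization
#'
#' Each column is divided by its standard deviation; the scaler can be fitted
#' on one set and applied to another (leakage-safe pipeline default).
#' Centering is not applied here — it is internal to [gi_pca()] — so the
#' network consumes unit-variance, uncentered descriptors. Zero-variance
#' columns are left unscaled with a warning.
#'
#' @param X raw proteins x descriptors matrix.
#' @param mode `"fit"` (estimate the scaler) or `"apply"` (use `scaler`).
#' @param scaler per-column sd vector from a previous fit.
#' @return List with `X` (normalized matrix) and `scaler`.
#' @export
normalize_features <- function(X, mode = c("fit", "apply"), scaler = NULL) {
  mode <- match.arg(mode)
  X <- as.matrix(X)
  if (any(!is.finite(X))) {
    bad <- which(!is.finite(X), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at row %d, column %d", bad[1L], bad[2L]),
         call. = FALSE)
  }
  if (mode == "fit") {
    if (nrow(X) < 2L) stop("fitting the scaler needs at least 2 rows", call. = FALSE)
    scaler <- apply(X, 2, stats::sd)
    if (any(scaler == 0)) {
      warning(sprintf("%d zero-variance column(s) left unscaled",
                      sum(scaler == 0)), call. = FALSE)
      scaler[scaler == 0] <- 1
    }
  } else if (is.null(scaler)) {
    stop("apply mode requires a fitted scaler", call. = FALSE)
  }
  list(X = sweep(X, 2, scaler, `/`), scaler = scaler)
}

#' PCA of a normalized descriptor matrix
#'
#' Centered, SVD-based principal component analysis. Loading signs are fixed
#' by making each column's largest-magnitude entry positive, so results are
#' fully deterministic.
#'
#' @param X normalized proteins x descriptors matrix.
#' @param k number of components.
#' @return List with `scores` (n x k), `loadings` (p x k, orthonormal),
#'   `explained_variance_ratio`, `center`.
#' @export
gi_pca <- function(X, k = 2L) {
  X <- as.matrix(X)
  if (k > min(nrow(X) - 1L, ncol(X))) {
    stop("k exceeds the available number of components", call. = FALSE)
  }
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  flip <- vapply(seq_len(k), function(j) {
    l <- pc$rotation[, j]
    if (l[which.max(abs(l))] < 0) -1 else 1
  }, numeric(1))
  scores <- sweep(pc$x[, seq_len(k), drop = FALSE], 2, flip, `*`)
  loadings <- sweep(pc$rotation[, seq_len(k), drop = FALSE], 2, flip, `*`)
  evr <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = scores, loadings = loadings,
       explained_variance_ratio = evr[seq_len(k)], center = pc$center)
}

#' Cluster proteins in PC space
#'
#' k-means (10 restarts, best inertia) on the first two principal-component
#' scores. Cluster labels are renumbered 1..k by descending cluster size
#' (ties by ascending PC1 centre) for reproducibility.
#'
#' @param pca result of [gi_pca()] (or any list with a `scores` matrix).
#' @param k number of clusters.
#' @param seed integer seed.
#' @return Integer vector of cluster labels in 1..k with attribute
#'   `"centers"`.
#' @export
cluster_scores <- function(pca, k = 4L, seed = 1L) {
  S <- pca$scores[, 1:2, drop = FALSE]
  if (nrow(S) < k) stop("fewer rows than clusters", call. = FALSE)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  km <- stats::kmeans(S, centers = k, nstart = 10L, iter.max = 100L)
  sizes <- as.vector(table(factor(km$cluster, levels = seq_len(k))))
  ord <- order(-sizes, km$centers[, 1L])
  relabel <- match(seq_len(k), ord)
  out <- relabel[km$cluster]
  attr(out, "centers") <- km$centers[ord, , drop = FALSE]
  attr(out, "k") <- k
  attr(out, "seed") <- seed
  out
}

#' Dominant secondary-structure class of a chain
#'
#' Majority rule over the per-residue classes; ties broken by the fixed
#' priority helix > sheet > coil.
#'
#' @param classes character vector of per-residue classes
#'   (`helix`/`sheet`/`coil`), or an annotation data.frame with `ss_class`.
#' @return One of `"helix"`, `"sheet"`, `"coil"`.
#' @export
majority_secondary_structure <- function(classes) {
  if (is.data.frame(classes)) classes <- classes$ss_class
  if (!length(classes)) stop("empty annotation", call. = FALSE)
  counts <- vapply(c("helix", "sheet", "coil"), function(cl) sum(classes == cl),
                   numeric(1))
  names(counts)[which.max(counts)]     # which.max takes the first maximum
}

#' Cluster composition summary
#'
#' Per-cluster fractions of each dominant secondary-structure class and of
#' flexible proteins, plus the median RMSF when values are supplied.
#'
#' @param clusters named (or id-aligned) cluster labels.
#' @param dominant named map id -> dominant class.
#' @param labels named map id -> flexibility label
#'   (`flexible`/`non_flexible`).
#' @param rmsf optional named map id -> RMSF scalar.
#' @return data.frame with one row per cluster.
#' @export
cluster_composition <- function(clusters, dominant, labels, rmsf = NULL) {
  ids <- names(clusters)
  if (is.null(ids)) ids <- as.character(seq_along(clusters))
  miss <- setdiff(ids, intersect(names(dominant), names(labels)))
  if (length(miss) == length(ids)) {
    stop("join error: no ids shared between clusters, classes and labels", call. = FALSE)
  }
  if (length(miss)) {
    stop(sprintf("join error: ids missing from classes or labels: %s",
                 paste(utils::head(miss, 5), collapse = ", ")), call. = FALSE)
  }
  do.call(rbind, lapply(sort(unique(clusters)), function(cl) {
    sel <- ids[clusters == cl]
    frac <- vapply(c("helix", "sheet", "coil"),
                   function(x) mean(dominant[sel] == x), numeric(1))
    data.frame(cluster = cl, n = length(sel),
               helix = frac["helix"], sheet = frac["sheet"], coil = frac["coil"],
               flexible_fraction = mean(labels[sel] == "flexible"),
               median_rmsf = if (is.null(rmsf)) NA_real_ else
                 stats::median(rmsf[sel]),
               row.names = NULL)
  }))
}
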