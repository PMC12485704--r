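# Evaluation metric suite: ROC/AUC with bootstrap CI, precision-recall,
# Youden threshold, confusion matrix, calibration, regression statistics.

#' ROC AUC by rank statistic
#'
#' The probability that a randomly chosen positive outranks a randomly chosen
#' negative, ties counting one half (equivalent to the Mann-Whitney U
#' statistic and to the trapezoidal area under the ROC curve).
#'
#' @param labels binary labels (0/1).
#' @param scores numeric scores, higher = more positive.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(labels, scores) {
  labels <- as.integer(labels)
  check_both_classes(labels)
  r <- rank(scores, ties.method = "average")
  n1 <- as.numeric(sum(labels == 1L)); n0 <- as.numeric(sum(labels == 0L))
  (sum(r[labels == 1L]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

check_both_classes <- function(labels) {
  if (length(unique(labels)) < 2L) {
    stop("metric error: both classes must be present", call. = FALSE)
  }
}

#' Percentile bootstrap confidence interval for the AUC
#'
#' Resamples test indices with replacement `n_boot` times (resamples missing
#' a class are redrawn) and reports the percentile interval.
#'
#' @param labels,scores as in [roc_auc()].
#' @param n_boot number of bootstrap resamples.
#' @param seed integer seed.
#' @param level confidence level.
#' @return Numeric vector `c(lo, hi)`.
#' @export
bootstrap_ci <- function(labels, scores, n_boot = 2000L, seed = 1L, level = 0.95) {
  labels <- as.integer(labels)
  check_both_classes(labels)
  n <- length(labels)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  aucs <- numeric(n_boot)
  for (b in seq_len(n_boot)) {
    repeat {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(labels[idx])) == 2L) break
    }
    aucs[b] <- roc_auc(labels[idx], scores[idx])
  }
  alpha <- (1 - level) / 2
  as.numeric(stats::quantile(aucs, c(alpha, 1 - alpha), names = FALSE, type = 7))
}

# candidate decision thresholds: predict positive when score >= t
candidate_thresholds <- function(scores) sort(unique(scores))

#' Precision-recall metrics
#'
#' Average precision as the step-wise area under the precision-recall curve
#' (sum over descending-score steps of precision times recall increment) and
#' the maximum F1 over all decision thresholds, ties broken toward the lower
#' (more sensitive) threshold.
#'
#' @param labels,scores as in [roc_auc()].
#' @return List with `average_precision`, `max_f1`, `f1_threshold`,
#'   `f1_precision`, `f1_recall`.
#' @export
pr_metrics <- function(labels, scores) {
  labels <- as.integer(labels)
  check_both_classes(labels)
  ord <- order(scores, decreasing = TRUE)
  y <- labels[ord]; s <- scores[ord]
  tp <- cumsum(y)
  fp <- cumsum(1 - y)
  # collapse tied scores to the last row of each tie block
  keep <- c(diff(s) != 0, TRUE)
  tp <- tp[keep]; fp <- fp[keep]
  n_pos <- sum(labels)
  prec <- tp / (tp + fp)
  rec <- tp / n_pos
  ap <- sum(diff(c(0, rec)) * prec)
  f1 <- 2 * prec * rec / (prec + rec)
  f1[!is.finite(f1)] <- 0
  best <- max(f1)
  # lowest threshold among maximizers = largest index (scores descending)
  bi <- max(which(f1 >= best - 1e-15))
  thr <- s[keep][bi]
  list(average_precision = ap, max_f1 = best, f1_threshold = thr,
       f1_precision = prec[bi], f1_recall = rec[bi])
}

#' Youden J optimal threshold
#'
#' The decision threshold (predict positive when score >= threshold)
#' maximizing TPR - FPR; ties broken toward the lower threshold.
#'
#' @param labels,scores as in [roc_auc()].
#' @return List with `threshold`, `j`, `tpr`, `fpr`.
#' @export
youden <- function(labels, scores) {
  labels <- as.integer(labels)
  check_both_classes(labels)
  ths <- candidate_thresholds(scores)
  n1 <- sum(labels == 1L); n0 <- sum(labels == 0L)
  best <- list(threshold = ths[1L], j = -Inf, tpr = NA, fpr = NA)
  for (t in ths) {
    pred <- scores >= t
    tpr <- sum(pred & labels == 1L) / n1
    fpr <- sum(pred & labels == 0L) / n0
    j <- tpr - fpr
    if (j > best$j + 1e-15) best <- list(threshold = t, j = j, tpr = tpr, fpr = fpr)
  }
  best
}

#' Row-normalized confusion matrix and calibration bins
#'
#' Confusion rows are the true classes (non-flexible = 0, flexible = 1),
#' normalized to sum to 1. Calibration uses `n_bins` equal-width probability
#' bins over \[0, 1\]; empty bins are omitted.
#'
#' @param labels,scores as in [roc_auc()].
#' @param threshold decision threshold (predict positive when score >=).
#' @param n_bins calibration bin count.
#' @return List with `confusion` (2 x 2) and `calibration` (data.frame of
#'   mean predicted, observed frequency and count per bin).
#' @export
confusion_and_calibration <- function(labels, scores, threshold, n_bins = 10L) {
  labels <- as.integer(labels)
  pred <- as.integer(scores >= threshold)
  cm <- matrix(0, 2, 2, dimnames = list(true = c("0", "1"), pred = c("0", "1")))
  for (a in 0:1) for (b in 0:1) cm[a + 1, b + 1] <- sum(labels == a & pred == b)
  rs <- rowSums(cm)
  cm_norm <- cm / ifelse(rs == 0, 1, rs)
  bins <- pmin(floor(scores * n_bins) + 1L, n_bins)
  cal <- do.call(rbind, lapply(sort(unique(bins)), function(b) {
    sel <- bins == b
    data.frame(bin = b, mean_predicted = mean(scores[sel]),
               observed_frequency = mean(labels[sel]), count = sum(sel))
  }))
  list(confusion = cm_norm, counts = cm, calibration = cal)
}

#' Regression metrics
#'
#' Pearson correlation, its square, the least-squares slope of predicted on
#' true, and the median absolute error.
#'
#' @param y_true,y_pred numeric vectors, length >= 3.
#' @return List with `pearson_r`, `r2`, `slope`, `median_abs_error`.
#' @export
regression_metrics <- function(y_true, y_pred) {
  if (length(y_true) < 3L) stop("need at least 3 observations", call. = FALSE)
  if (stats::sd(y_true) == 0 || stats::sd(y_pred) == 0) {
    stop("metric error: zero variance in inputs", call. = FALSE)
  }
  r <- stats::cor(y_true, y_pred)
  slope <- stats::cov(y_true, y_pred) / stats::var(y_true)
  list(pearson_r = r, r2 = r^2, slope = slope,
       median_abs_error = stats::median(abs(y_pred - y_true)))
}

#' Full evaluation report for a classifier
#'
#' Bundles AUC with bootstrap CI, average precision, max F1, the Youden
#' operating point, the row-normalized confusion matrix at the Youden
#' threshold, calibration bins, and per-cluster AUC when cluster labels are
#' given.
#'
#' @param labels,scores test labels and scores.
#' @param clusters optional cluster assignment aligned with labels.
#' @param n_boot,seed bootstrap controls.
#' @return An `eval_report` list.
#' @export
eval_report <- function(labels, scores, clusters = NULL, n_boot = 2000L, seed = 1L) {
  auc <- roc_auc(labels, scores)
  ci <- bootstrap_ci(labels, scores, n_boot = n_boot, seed = seed)
  pr <- pr_metrics(labels, scores)
  yj <- youden(labels, scores)
  cc <- confusion_and_calibration(labels, scores, yj$threshold)
  per_cluster <- NULL
  if (!is.null(clusters)) {
    per_cluster <- vapply(sort(unique(clusters)), function(cl) {
      sel <- clusters == cl
      if (length(unique(labels[sel])) < 2L) return(NA_real_)
      roc_auc(labels[sel], scores[sel])
    }, numeric(1))
    names(per_cluster) <- sort(unique(clusters))
  }
  structure(list(auc = auc, auc_ci = ci,
                 average_precision = pr$average_precision,
                 max_f1 = pr$max_f1, f1_precision = pr$f1_precision,
                 f1_recall = pr$f1_recall,
                 youden_threshold = yj$threshold, youden_j = yj$j,
                 tpr = yj$tpr, fpr = yj$fpr,
                 confusion = cc$confusion, calibration = cc$calibration,
                 per_cluster_auc = per_cluster, n = length(labels)),
            class = "eval_report")
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("AUC %.3f (95%% CI %.3f-%.3f), AP %.3f, max F1 %.3f\n",
              x$auc, x$auc_ci[1], x$auc_ci[2], x$average_precision, x$max_f1))
  cat(sprintf("Youden threshold %.3f (TPR %.3f, FPR %.3f); n = %d\n",
              x$youden_threshold, x$tpr, x$fpr, x$n))
  invisible(x)
}
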