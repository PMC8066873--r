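# Multivariate data-driven analysis: leave-one-out cross-validated linear
# regression, ROC/AUC with null z-statistic, and bootstrap loading z-scores.

#' Leave-one-out cross-validated linear regression scores
#'
#' For each subject, an ordinary least squares regression of the binary label
#' (AD = 1, HC = 0) on the features (intercept included) is fitted on the
#' remaining subjects and evaluated on the held-out one. Larger out-of-fold
#' scores indicate AD-like feature patterns.
#'
#' @param X subjects x features matrix.
#' @param y binary labels (1 = AD, 0 = HC).
#' @return List of class `nc_loocv`: `scores` (out-of-fold predictions),
#'   `loadings` (per-feature weight averaged over folds), `fold_loadings`
#'   (features x folds), `y`.
#' @export
loocv_scores <- function(X, y) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 3) stop_param("need at least 3 subjects for leave-one-out fitting")
  if (ncol(X) >= n - 1) stop_param("more features than leave-one-out fits can support")
  if (length(unique(y)) < 2) stop_data("both classes must be present")
  if (anyNA(X) || !all(is.finite(X))) stop_data("features must be finite")
  Xi <- cbind(1, X)
  scores <- numeric(n)
  fold_loadings <- matrix(0, ncol(X), n,
                          dimnames = list(colnames(X), NULL))
  for (i in seq_len(n)) {
    fit <- stats::lm.fit(Xi[-i, , drop = FALSE], y[-i])
    if (fit$rank < ncol(Xi)) stop_numeric("singular design in fold ", i)
    scores[i] <- drop(Xi[i, ] %*% fit$coefficients)
    fold_loadings[, i] <- fit$coefficients[-1]
  }
  structure(list(scores = scores, loadings = rowMeans(fold_loadings),
                 fold_loadings = fold_loadings, y = y),
            class = "nc_loocv")
}

#' Null-hypothesis standard error of the AUC
#'
#' Closed-form standard error of an AUC for group sizes `n1`, `n2`
#' evaluated at the null AUC of 0.5 (rank-based closed form):
#' `SE0^2 = [A(1-A) + (n1-1)(Q1-A^2) + (n2-1)(Q2-A^2)] / (n1 n2)` with
#' `Q1 = A/(2-A)`, `Q2 = 2A^2/(1+A)`; at `A = 0.5` both bracketed
#' differences equal 1/12, so `SE0^2 = [1/4 + (n1+n2-2)/12] / (n1 n2)`.
#'
#' @param n1,n2 group sizes.
#' @return Standard error at AUC = 0.5.
#' @export
auc_null_se <- function(n1, n2) {
  A <- 0.5
  q1 <- A / (2 - A)
  q2 <- 2 * A^2 / (1 + A)
  sqrt((A * (1 - A) + (n1 - 1) * (q1 - A^2) + (n2 - 1) * (q2 - A^2)) / (n1 * n2))
}

#' Significance z-statistic of an AUC against chance
#'
#' `z = (AUC - 0.5) / SE0` with the null standard error of [auc_null_se()],
#' and a one-sided upper-tail normal p-value.
#'
#' @param auc observed area under the ROC curve.
#' @param n1,n2 group sizes (positives, negatives).
#' @return List with `z` and `p`.
#' @export
auc_null_z <- function(auc, n1, n2) {
  z <- (auc - 0.5) / auc_null_se(n1, n2)
  list(z = z, p = stats::pnorm(z, lower.tail = FALSE))
}

#' ROC analysis of classifier scores
#'
#' The AUC is the normalized Mann-Whitney statistic (ties counted one half);
#' the significance z is the AUC against its null standard error.
#'
#' @param scores numeric classifier outputs (larger = more AD-like).
#' @param labels binary labels (1 = AD/positive).
#' @return Object of class `nc_roc`: `auc`, `z`, `p`, `thresholds`,
#'   `sensitivity`, `specificity`, `n1`, `n2`.
#' @export
roc_analysis <- function(scores, labels) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop_data("both classes must be present")
  n1 <- sum(labels == 1)
  n2 <- sum(labels == 0)
  r <- rank(scores)          # midranks: ties count 1/2
  auc <- (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n2)
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE))
  sens <- vapply(thr, function(t) mean(scores[labels == 1] >= t), numeric(1))
  spec <- vapply(thr, function(t) mean(scores[labels == 0] < t), numeric(1))
  zz <- auc_null_z(auc, n1, n2)
  structure(list(auc = auc, z = zz$z, p = zz$p, thresholds = thr,
                 sensitivity = sens, specificity = spec, n1 = n1, n2 = n2,
                 scores = scores, labels = labels),
            class = "nc_roc")
}

#' @export
print.nc_roc <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f (z = %.3f, p = %.3g; n1 = %d, n2 = %d)\n",
              x$auc, x$z, x$p, x$n1, x$n2))
  invisible(x)
}

#' @export
plot.nc_roc <- function(x, ...) {
  graphics::plot(1 - x$specificity, x$sensitivity, type = "s",
                 xlab = "1 - specificity", ylab = "sensitivity",
                 main = sprintf("ROC (AUC = %.3f)", x$auc), ...)
  graphics::abline(0, 1, lty = 2, col = "grey")
  invisible(x)
}

#' Confusion matrix at an operating threshold
#'
#' Scores at or above the threshold predict the positive (AD) class. When no
#' threshold is supplied, the Youden-optimal one (maximizing sensitivity +
#' specificity - 1) is used.
#'
#' @param scores,labels as in [roc_analysis()].
#' @param threshold operating threshold, or `NULL` for the Youden optimum.
#' @return Object of class `nc_confusion`: counts `tp`, `fn`, `fp`, `tn`,
#'   `sensitivity`, `specificity`, `threshold`.
#' @export
confusion_at_threshold <- function(scores, labels, threshold = NULL) {
  labels <- as.integer(labels)
  if (length(unique(labels)) < 2) stop_data("both classes must be present")
  if (is.null(threshold)) {
    roc <- roc_analysis(scores, labels)
    threshold <- roc$thresholds[which.max(roc$sensitivity + roc$specificity)]
  }
  pred <- scores >= threshold
  structure(confusion_from_counts(tp = sum(pred & labels == 1),
                                  fn = sum(!pred & labels == 1),
                                  fp = sum(pred & labels == 0),
                                  tn = sum(!pred & labels == 0),
                                  threshold = threshold),
            class = "nc_confusion")
}

#' Sensitivity and specificity from confusion counts
#'
#' @param tp,fn,fp,tn nonnegative counts.
#' @param threshold optional operating threshold stored with the result.
#' @return List with the counts, `sensitivity = tp/(tp+fn)` and
#'   `specificity = tn/(tn+fp)`.
#' @export
confusion_from_counts <- function(tp, fn, fp, tn, threshold = NA_real_) {
  if (any(c(tp, fn, fp, tn) < 0)) stop_param("counts must be nonnegative")
  list(tp = tp, fn = fn, fp = fp, tn = tn,
       sensitivity = tp / (tp + fn), specificity = tn / (tn + fp),
       threshold = threshold)
}

#' @export
print.nc_confusion <- function(x, ...) {
  cat(sprintf("Confusion (threshold %.4g): tp %d fn %d fp %d tn %d | sens %.1f%% spec %.1f%%\n",
              x$threshold, x$tp, x$fn, x$fp, x$tn,
              100 * x$sensitivity, 100 * x$specificity))
  invisible(x)
}

#' Bootstrap z-scores of the classifier loadings
#'
#' The reported loading per feature is the mean over leave-one-out folds; its
#' variability is estimated by refitting the full-sample regression on
#' bootstrap resamples of the subjects (default 10,000). Resamples containing
#' a single class are redrawn (counted in `n_redrawn`).
#'
#' @param X,y as in [loocv_scores()].
#' @param n_boot number of bootstrap resamples.
#' @param seed RNG seed.
#' @param loocv optional precomputed [loocv_scores()] result.
#' @return Object of class `nc_boot`: `loadings`, `sd_boot`, `z`, `seed`,
#'   `n_boot`, `n_redrawn`.
#' @export
bootstrap_loading_z <- function(X, y, n_boot = 10000, seed = 1, loocv = NULL) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 10) stop_param("need at least 10 subjects for the bootstrap")
  loocv <- loocv %||% loocv_scores(X, y)
  Xi <- cbind(1, X)
  set.seed(seed)
  B <- matrix(0, ncol(X), n_boot)
  n_redrawn <- 0L
  for (b in seq_len(n_boot)) {
    for (try in 1:1000) {
      idx <- sample.int(n, n, replace = TRUE)
      if (length(unique(y[idx])) > 1) {
        fit <- stats::lm.fit(Xi[idx, , drop = FALSE], y[idx])
        if (fit$rank == ncol(Xi)) break   # resample must support a full fit
      }
      n_redrawn <- n_redrawn + 1L
      if (try == 1000)
        stop_numeric("could not draw a full-rank bootstrap resample")
    }
    B[, b] <- fit$coefficients[-1]
  }
  sd_boot <- apply(B, 1, stats::sd)
  if (any(sd_boot == 0)) stop_numeric("degenerate bootstrap loading distribution")
  structure(list(loadings = loocv$loadings, sd_boot = sd_boot,
                 z = loocv$loadings / sd_boot, seed = seed, n_boot = n_boot,
                 n_redrawn = n_redrawn),
            class = "nc_boot")
}

#' Classify a cohort from a feature matrix
#'
#' Convenience wrapper chaining [loocv_scores()], [roc_analysis()],
#' [confusion_at_threshold()] (Youden) and optionally
#' [bootstrap_loading_z()].
#'
#' @param X,y feature matrix and binary labels.
#' @param n_boot bootstrap resamples for loading z-scores; 0 skips the
#'   bootstrap.
#' @param seed bootstrap seed.
#' @return Object of class `nc_classifier`: `loocv`, `roc`, `confusion`,
#'   `boot` (or `NULL`).
#' @export
nc_classify <- function(X, y, n_boot = 10000, seed = 1) {
  cv <- loocv_scores(X, y)
  roc <- roc_analysis(cv$scores, y)
  conf <- confusion_at_threshold(cv$scores, y)
  boot <- if (n_boot > 0) bootstrap_loading_z(X, y, n_boot, seed, loocv = cv)
  structure(list(loocv = cv, roc = roc, confusion = conf, boot = boot),
            class = "nc_classifier")
}

#' @export
print.nc_classifier <- function(x, ...) {
  print(x$roc)
  print(x$confusion)
  if (!is.null(x$boot)) {
    cat("Loadings (z by bootstrap):\n")
    print(round(rbind(loading = x$boot$loadings, z = x$boot$z), 3))
  }
  invisible(x)
}
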