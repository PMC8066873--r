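# LOO-CV linear classifier, ROC/AUC and bootstrap loadings.

test_that("leave-one-out scores separate a separable feature perfectly", {
  X <- matrix(c(rnorm(10, 5, 0.1), rnorm(10, 0, 0.1)), ncol = 1)
  y <- rep(c(1, 0), each = 10)
  cv <- loocv_scores(X, y)
  expect_equal(roc_analysis(cv$scores, y)$auc, 1)
  expect_error(loocv_scores(X[1:2, , drop = FALSE], y[1:2]),
               class = "nvc_param_error")
})

test_that("permuted labels give chance-level cross-validated AUC", {
  set.seed(35)
  X <- matrix(rnorm(35 * 6), 35)
  y <- sample(rep(c(1, 0), c(17, 18)))
  auc <- roc_analysis(loocv_scores(X, y)$scores, y)$auc
  expect_gte(auc, 0.2)
  expect_lte(auc, 0.8)
  aucs <- vapply(1:100, function(i) {
    yp <- sample(y)
    roc_analysis(loocv_scores(X, yp)$scores, yp)$auc
  }, numeric(1))
  # leave-one-out regression scores are pessimistically biased under the
  # null (the held-out label pulls each training fit the other way), so the
  # permutation mean sits slightly below 0.5
  expect_gte(mean(aucs), 0.40)
  expect_lte(mean(aucs), 0.55)
})

test_that("AUC equals exhaustive pair enumeration and pROC agrees", {
  set.seed(20)
  for (r in 1:30) {
    n1 <- sample(3:25, 1); n2 <- sample(3:25, 1)
    scores <- round(c(rnorm(n1, 0.5), rnorm(n2)), sample(c(1, 8), 1))
    labels <- rep(c(1, 0), c(n1, n2))
    expect_equal(roc_analysis(scores, labels)$auc,
                 auc_by_enumeration(scores, labels), tolerance = 1e-12)
  }
  skip_if_not_installed("pROC")
  set.seed(21)
  scores <- rnorm(35); labels <- rep(c(1, 0), c(17, 18))
  expect_equal(roc_analysis(scores, labels)$auc,
               as.numeric(suppressMessages(pROC::auc(labels, scores))),
               tolerance = 1e-12)
})

test_that("the ROC curve is monotone and ties give chance AUC", {
  roc <- roc_analysis(rep(1, 10), rep(c(1, 0), 5))
  expect_equal(roc$auc, 0.5)
  expect_equal(roc$z, 0)
  set.seed(22)
  r2 <- roc_analysis(rnorm(30), rep(c(1, 0), 15))
  expect_true(all(diff(r2$sensitivity) >= 0))   # thresholds descend
  expect_true(all(diff(r2$specificity) <= 0))
  expect_error(roc_analysis(rnorm(5), rep(1, 5)), class = "nvc_data_error")
})

test_that("confusion matrices follow the threshold convention", {
  scores <- c(0.9, 0.8, 0.3, 0.7, 0.2, 0.1)
  labels <- c(1, 1, 1, 0, 0, 0)
  cm <- confusion_at_threshold(scores, labels, 0.5)
  expect_identical(c(cm$tp, cm$fn, cm$fp, cm$tn), c(2L, 1L, 1L, 2L))
  low <- confusion_at_threshold(scores, labels, -1)
  expect_equal(low$sensitivity, 1)
  expect_equal(low$specificity, 0)
  high <- confusion_at_threshold(scores, labels, 2)
  expect_equal(high$sensitivity, 0)
  expect_equal(high$specificity, 1)
  ycm <- confusion_at_threshold(scores, labels)      # Youden default
  expect_gte(ycm$sensitivity + ycm$specificity,
             cm$sensitivity + cm$specificity)
})

test_that("bootstrap loading z-scores behave under signal and null", {
  set.seed(30)
  y <- rep(c(1, 0), c(17, 18))
  X <- cbind(informative = y + rnorm(35, sd = 0.1), noise = rnorm(35))
  bz <- bootstrap_loading_z(X, y, n_boot = 500, seed = 3)
  expect_gt(bz$z["informative"], 5)
  bz2 <- bootstrap_loading_z(X, y, n_boot = 500, seed = 3)
  expect_identical(bz$z, bz2$z)
  # pure-noise features rarely reach |z| > 2
  hits <- vapply(1:10, function(r) {
    set.seed(400 + r)
    Xn <- matrix(rnorm(35), ncol = 1)
    abs(bootstrap_loading_z(Xn, y, n_boot = 300, seed = r)$z) < 2
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})
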