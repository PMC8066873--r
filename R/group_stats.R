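# Univariate group inference on the NC and unimodal metrics.

nc_ttest_result <- function(ht, n1, n2 = NA_integer_, mean_diff) {
  structure(list(t = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, mean_diff = mean_diff, n1 = n1, n2 = n2),
            class = "nc_ttest")
}

#' @export
print.nc_ttest <- function(x, ...) {
  cat(sprintf("t = %.3f, df = %d, p = %.4g (mean difference %.4g)\n",
              x$t, x$df, x$p, x$mean_diff))
  invisible(x)
}

#' One-sample t-test of NC against zero
#'
#' Two-tailed one-sample t-test with `df = n - 1`, used to test whether a
#' group's mean coupling differs from zero.
#'
#' @param values numeric vector (per-subject metric values).
#' @param null_value hypothesized mean (default 0).
#' @return Object of class `nc_ttest`: `t`, `df`, `p`, `mean_diff`, `n1`.
#' @export
one_sample_t <- function(values, null_value = 0) {
  if (length(values) < 2) stop_param("need at least 2 values")
  if (stats::sd(values) == 0) stop_data("zero variance: t-statistic undefined")
  ht <- stats::t.test(values, mu = null_value)
  nc_ttest_result(ht, length(values), mean_diff = mean(values) - null_value)
}

#' Pooled-variance two-sample t-test
#'
#' Two-tailed two-sample t-test with pooled variance, `df = n1 + n2 - 2`
#' (e.g. df = 33 for groups of 17 and 18).
#'
#' @param a,b numeric vectors for the two groups.
#' @return Object of class `nc_ttest`.
#' @export
two_sample_t <- function(a, b) {
  if (length(a) < 2 || length(b) < 2) stop_param("need at least 2 values per group")
  if (stats::sd(a) == 0 && stats::sd(b) == 0)
    stop_data("zero variance in both groups: t-statistic undefined")
  ht <- stats::t.test(a, b, var.equal = TRUE)
  nc_ttest_result(ht, length(a), length(b), mean_diff = mean(a) - mean(b))
}

#' Group statistics for a cohort metric table
#'
#' For each metric column: one-sample t-tests against zero within each group
#' and the pooled two-sample AD-vs-HC comparison. No multiple-comparison
#' correction is applied to the six univariate tests; the multivariate
#' analysis serves as the guard against false positives.
#'
#' @param metrics subjects x metrics matrix (see [nc_metrics_table()]).
#' @param labels binary vector, 1 = AD, 0 = HC.
#' @return Data frame with one row per metric: group means and the `t`, `df`,
#'   `p` triplets of the three tests.
#' @export
nc_group_tests <- function(metrics, labels) {
  metrics <- as.matrix(metrics)
  if (length(labels) != nrow(metrics)) stop_param("labels/metrics mismatch")
  if (length(unique(labels)) < 2) stop_data("both groups must be present")
  ad <- labels == 1
  do.call(rbind, lapply(seq_len(ncol(metrics)), function(j) {
    v <- metrics[, j]
    t_ad <- one_sample_t(v[ad]); t_hc <- one_sample_t(v[!ad])
    t_2 <- two_sample_t(v[ad], v[!ad])
    data.frame(metric = colnames(metrics)[j] %||% paste0("m", j),
               mean_AD = mean(v[ad]), mean_HC = mean(v[!ad]),
               t_AD_vs_0 = t_ad$t, p_AD_vs_0 = t_ad$p,
               t_HC_vs_0 = t_hc$t, p_HC_vs_0 = t_hc$p,
               t_AD_vs_HC = t_2$t, df = t_2$df, p_AD_vs_HC = t_2$p)
  }))
}
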