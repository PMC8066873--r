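# Recording-time and channel-count sweeps of the full NC + classification
# analysis.

# Trims adapted to the window length: the defaults (5 s edge, 30 s HRF
# transient) are kept whenever the window affords them and shrink smoothly
# for short windows so that the GLM remains estimable down to 15 s windows
# (where the fit is deliberately left as over-parameterized as the short
# record allows).
adaptive_trims <- function(window_s) {
  spare <- max(0, window_s - 24)
  edge <- min(5, spare / 10)
  trim <- min(30, max(0, window_s - 24 - 2 * edge))
  list(edge_trim_s = edge, trim_s = trim,
       min_row_factor = if (window_s >= 90) 3 else 1,
       min_rows = if (window_s >= 90) 30 else 8)
}

truncate_subject <- function(subject, window_s) {
  eeg <- subject$eeg
  intens <- subject$intensity
  dur <- ncol(eeg$data) / eeg$fs
  t0 <- (dur - window_s) / 2
  e_idx <- (round(t0 * eeg$fs) + 1):(round(t0 * eeg$fs) + round(window_s * eeg$fs))
  o_idx <- (round(t0 * intens$fs) + 1):(round(t0 * intens$fs) + floor(window_s * intens$fs))
  o_idx <- o_idx[o_idx <= dim(intens$data)[3]]
  subject$eeg <- eeg_recording(eeg$data[, e_idx, drop = FALSE], eeg$fs,
                               eeg$channel_labels)
  subject$intensity <- optical_intensity(intens$data[, , o_idx, drop = FALSE],
                                         intens$fs, intens$wavelengths,
                                         intens$geometry)
  subject
}

subset_eeg_channels <- function(subject, channels) {
  eeg <- subject$eeg
  subject$eeg <- eeg_recording(eeg$data[channels, , drop = FALSE], eeg$fs,
                               eeg$channel_labels[channels])
  subject
}

run_cohort_analysis <- function(subjects, labels, n_boot = 0, seed = 1, ...) {
  fits <- lapply(subjects, nc_fit, ...)
  X <- nc_metrics_table(fits)
  cls <- nc_classify(X, labels, n_boot = n_boot, seed = seed)
  list(fits = fits, metrics = X, classifier = cls)
}

#' Classification performance as a function of recording time
#'
#' Re-runs the full NC estimation and leave-one-out classification on
#' centered windows of increasing length. The full-length window reproduces
#' the full-signal analysis exactly. Edge and HRF-transient trims shrink for
#' windows that cannot afford the full-length defaults.
#'
#' @param cohort a `synthetic_cohort` (or list with `subjects` and `labels`).
#' @param step_s window step in seconds (default 15).
#' @param max_s largest window (default: the full recording duration).
#' @param n_boot bootstrap resamples for per-window loading z-scores
#'   (0 skips the bootstrap and reports `NA` z).
#' @param seed bootstrap seed.
#' @param ... forwarded to [nc_fit()] (e.g. `run_ica`).
#' @return Object of class `nc_sweep`: data frame `results` (`axis`, `auc`),
#'   `loadings` and `z` (features x windows), `axis_unit`.
#' @export
sweep_recording_time <- function(cohort, step_s = 15, max_s = NULL,
                                 n_boot = 0, seed = 1, ...) {
  dur <- ncol(cohort$subjects[[1]]$eeg$data) / cohort$subjects[[1]]$eeg$fs
  max_s <- max_s %||% dur
  windows <- seq(step_s, max_s, by = step_s)
  keep <- windows <= dur + 1e-9
  if (!all(keep)) warning("skipping windows longer than the recording")
  windows <- windows[keep]
  res <- lapply(windows, function(w) {
    tr <- adaptive_trims(w)
    subs <- lapply(cohort$subjects, truncate_subject, window_s = w)
    an <- run_cohort_analysis(subs, cohort$labels, n_boot = n_boot, seed = seed,
                              edge_trim_s = tr$edge_trim_s, trim_s = tr$trim_s,
                              min_row_factor = tr$min_row_factor,
                              min_rows = tr$min_rows, ...)
    an$classifier
  })
  sweep_result(windows, res, "seconds", seed)
}

#' Classification performance as a function of EEG channel count
#'
#' Re-runs the analysis on randomly drawn EEG channel subsets of increasing
#' size (one seeded draw per count). The full channel count uses all channels
#' and reproduces the full analysis exactly.
#'
#' @param cohort a `synthetic_cohort`.
#' @param step channel-count step (default 4).
#' @param max_channels largest count (default: all channels).
#' @param seed seed for the channel draws (and bootstrap).
#' @param n_boot bootstrap resamples per count (0 skips).
#' @param ... forwarded to [nc_fit()].
#' @return Object of class `nc_sweep` (axis in channels).
#' @export
sweep_channel_count <- function(cohort, step = 4, max_channels = NULL,
                                seed = 1, n_boot = 0, ...) {
  n_ch <- nrow(cohort$subjects[[1]]$eeg$data)
  max_channels <- max_channels %||% n_ch
  counts <- seq(step, max_channels, by = step)
  keep <- counts <= n_ch
  if (!all(keep)) warning("skipping counts above the available channels")
  counts <- counts[keep]
  draw_seeds <- derive_seeds(seed, length(counts))
  res <- lapply(seq_along(counts), function(i) {
    k <- counts[i]
    chans <- if (k == n_ch) seq_len(n_ch) else {
      set.seed(draw_seeds[i]); sort(sample.int(n_ch, k))
    }
    subs <- lapply(cohort$subjects, subset_eeg_channels, channels = chans)
    run_cohort_analysis(subs, cohort$labels, n_boot = n_boot, seed = seed,
                        ...)$classifier
  })
  sweep_result(counts, res, "channels", seed)
}

sweep_result <- function(axis, classifiers, axis_unit, seed) {
  auc <- vapply(classifiers, function(cl) cl$roc$auc, numeric(1))
  L <- vapply(classifiers, function(cl) cl$loocv$loadings,
              numeric(length(classifiers[[1]]$loocv$loadings)))
  Z <- vapply(classifiers, function(cl)
    if (is.null(cl$boot)) rep(NA_real_, nrow(L)) else cl$boot$z,
    numeric(nrow(L)))
  structure(list(results = data.frame(axis = axis, auc = auc),
                 loadings = L, z = Z, axis_unit = axis_unit, seed = seed),
            class = "nc_sweep")
}

#' @export
print.nc_sweep <- function(x, ...) {
  cat(sprintf("Analysis sweep over %s:\n", x$axis_unit))
  print(x$results, row.names = FALSE)
  invisible(x)
}

#' @export
plot.nc_sweep <- function(x, ...) {
  graphics::plot(x$results$axis, x$results$auc, type = "b",
                 xlab = x$axis_unit, ylab = "LOO-CV AUC",
                 main = "Classification vs problem size", ylim = c(0, 1), ...)
  graphics::abline(h = 0.5, lty = 2, col = "grey")
  invisible(x)
}
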