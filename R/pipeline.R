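# Configuration, provenance and the end-to-end pipeline driver.

#' Pipeline configuration
#'
#' Collects every tunable of the end-to-end analysis with defaults matching
#' the reference acquisition and analysis settings: 250 Hz EEG, 10.42 Hz
#' fNIRS, canonical bands, 0.01--0.4 Hz hemodynamic band, 35/15 mm long/short
#' geometry, 1 Hz GLM rate, 10,000 bootstrap resamples and 15 s / 4-channel
#' sweep steps.
#'
#' @param n_ad,n_hc simulated group sizes.
#' @param duration_s recording duration (s).
#' @param n_channels EEG channel count.
#' @param fs_eeg,fs_fnirs sampling rates (Hz).
#' @param bands band definitions, see [eeg_bands()].
#' @param od_band hemodynamic OD band-pass edges (Hz).
#' @param target_fs GLM rate (Hz).
#' @param trim_s,edge_trim_s transient trims (s).
#' @param run_ica run automatic ICA artifact removal per subject.
#' @param kurtosis_threshold wavelet motion-correction threshold.
#' @param n_boot bootstrap resamples for loading z-scores.
#' @param sweep_time_step_s,sweep_channel_step sweep grid steps.
#' @param seed master seed.
#' @param specs group coupling specifications (list `AD`, `HC`).
#' @return Validated list of class `nc_config`.
#' @export
nc_config <- function(n_ad = 17, n_hc = 18, duration_s = 300, n_channels = 128,
                      fs_eeg = 250, fs_fnirs = 10.42, bands = eeg_bands(),
                      od_band = c(0.01, 0.4), target_fs = 1, trim_s = 30,
                      edge_trim_s = 5, run_ica = FALSE,
                      kurtosis_threshold = 3.3, n_boot = 10000,
                      sweep_time_step_s = 15, sweep_channel_step = 4,
                      seed = 1, specs = default_coupling_specs()) {
  cfg <- as.list(environment())
  for (b in names(cfg$bands)) {
    e <- cfg$bands[[b]]
    if (length(e) != 2 || e[1] <= 0 || e[2] <= e[1])
      stop_param("band '", b, "' must have 0 < low < high")
  }
  if (cfg$od_band[1] <= 0 || cfg$od_band[2] <= cfg$od_band[1])
    stop_param("invalid OD band edges")
  if (cfg$n_ad + cfg$n_hc < 1) stop_param("empty cohort")
  if (cfg$duration_s < 30) stop_param("duration must be at least 30 s")
  structure(cfg, class = "nc_config")
}

config_hash <- function(cfg) {
  f <- tempfile()
  on.exit(unlink(f))
  saveRDS(cfg[order(names(cfg))], f)
  unname(tools::md5sum(f))
}

#' Run the full analysis pipeline
#'
#' Simulates (or accepts) a cohort, estimates per-subject NC metrics and
#' unimodal powers, computes univariate group statistics and fits the
#' leave-one-out classifiers on the NC, EEG-power and fNIRS-power feature
#' sets, optionally followed by the recording-time and channel-count sweeps.
#'
#' @param config an [nc_config()].
#' @param cohort optional precomputed `synthetic_cohort`; by default one is
#'   simulated from the config.
#' @param sweeps also run the two sweeps (slow).
#' @return Object of class `nc_results`: `metrics`, `powers`, `group_tests`,
#'   `classifiers` (nc / eeg / fnirs), optional `sweeps`, `config`, `seed`,
#'   `config_hash`, `fits`.
#' @export
run_pipeline <- function(config = nc_config(), cohort = NULL, sweeps = FALSE) {
  stopifnot(inherits(config, "nc_config"))
  cohort <- cohort %||% simulate_cohort(
    spec_ad = config$specs$AD, spec_hc = config$specs$HC,
    n_ad = config$n_ad, n_hc = config$n_hc, duration_s = config$duration_s,
    seed = config$seed, n_channels = config$n_channels,
    fs_eeg = config$fs_eeg, fs_fnirs = config$fs_fnirs)
  fit_args <- list(bands = config$bands, run_ica = config$run_ica,
                   edge_trim_s = config$edge_trim_s, trim_s = config$trim_s,
                   target_fs = config$target_fs,
                   kurtosis_threshold = config$kurtosis_threshold)
  fits <- lapply(seq_along(cohort$subjects), function(i) {
    tryCatch(do.call(nc_fit, c(list(cohort$subjects[[i]]), fit_args)),
             error = function(e) stop("NC estimation failed for subject ", i,
                                      ": ", conditionMessage(e), call. = FALSE))
  })
  X <- nc_metrics_table(fits)
  P <- power_metrics_table(fits)
  y <- cohort$labels
  tests <- nc_group_tests(X, y)
  power_tests <- nc_group_tests(cbind(P$eeg, P$fnirs), y)
  classifiers <- list(
    nc = nc_classify(X, y, n_boot = config$n_boot, seed = config$seed),
    eeg = nc_classify(P$eeg, y, n_boot = 0),
    fnirs = nc_classify(P$fnirs, y, n_boot = 0))
  sw <- NULL
  if (sweeps)
    sw <- list(time = sweep_recording_time(cohort, step_s = config$sweep_time_step_s,
                                           run_ica = config$run_ica),
               channels = sweep_channel_count(cohort, step = config$sweep_channel_step,
                                              seed = config$seed,
                                              run_ica = config$run_ica))
  structure(list(metrics = X, powers = P, group_tests = tests,
                 power_tests = power_tests, classifiers = classifiers,
                 sweeps = sw, labels = y, fits = fits, config = config,
                 seed = config$seed, config_hash = config_hash(config)),
            class = "nc_results")
}

#' @export
print.nc_results <- function(x, ...) {
  cat(sprintf("NC pipeline results: %d subjects (%d AD, %d HC), seed %d, config %s\n",
              length(x$labels), sum(x$labels == 1), sum(x$labels == 0),
              x$seed, substr(x$config_hash, 1, 8)))
  cat("\nGroup comparison (AD vs HC) of the six NC metrics:\n")
  print(x$group_tests[, c("metric", "mean_AD", "mean_HC", "t_AD_vs_HC", "df",
                          "p_AD_vs_HC")], row.names = FALSE, digits = 3)
  cat("\nClassifiers (LOO-CV):\n")
  for (nm in names(x$classifiers)) {
    cat(sprintf("  %-5s ", nm)); print(x$classifiers[[nm]]$roc)
  }
  invisible(x)
}

#' Write pipeline results as tidy CSV tables
#'
#' Emits `metrics.csv` (per-subject NC metrics and powers with provenance
#' columns), `group_tests.csv`, `scores.csv`, `roc.csv`, `loadings.csv` and
#' a JSON manifest.
#'
#' @param results an `nc_results`.
#' @param path output directory.
#' @return `path`, invisibly.
#' @export
write_results <- function(results, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  prov <- data.frame(config_hash = results$config_hash, seed = results$seed)
  met <- data.frame(subject = seq_len(nrow(results$metrics)),
                    label = results$labels, results$metrics,
                    results$powers$eeg, results$powers$fnirs, prov,
                    check.names = FALSE)
  utils::write.csv(met, file.path(path, "metrics.csv"), row.names = FALSE)
  utils::write.csv(cbind(results$group_tests, prov),
                   file.path(path, "group_tests.csv"), row.names = FALSE)
  cls <- results$classifiers$nc
  utils::write.csv(data.frame(subject = seq_along(cls$loocv$scores),
                              label = results$labels,
                              score = cls$loocv$scores, prov),
                   file.path(path, "scores.csv"), row.names = FALSE)
  utils::write.csv(data.frame(threshold = cls$roc$thresholds,
                              sensitivity = cls$roc$sensitivity,
                              specificity = cls$roc$specificity),
                   file.path(path, "roc.csv"), row.names = FALSE)
  ld <- data.frame(feature = names(cls$loocv$loadings),
                   loading = cls$loocv$loadings)
  if (!is.null(cls$boot)) { ld$sd_boot <- cls$boot$sd_boot; ld$z <- cls$boot$z }
  utils::write.csv(ld, file.path(path, "loadings.csv"), row.names = FALSE)
  jsonlite::write_json(list(seed = results$seed, config_hash = results$config_hash,
                            auc = vapply(results$classifiers,
                                         function(cl) cl$roc$auc, numeric(1))),
                       file.path(path, "manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(path)
}
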