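# Per-subject end-to-end NC estimation: the package's central fitting
# function and its S3 methods.

#' Estimate neurovascular coupling for one subject
#'
#' Runs the full per-subject analysis: EEG broadband + notch filtering,
#' optional automatic ICA artifact removal, band power envelopes (theta,
#' alpha, beta) and their first temporal principal components; optical
#' intensities to optical density, kurtosis-based wavelet motion correction,
#' hemodynamic band-pass and modified Beer-Lambert inversion to HbO/HbR; then
#' one standardized GLM per long channel and chromophore with the three
#' HRF-convolved global envelopes as predictors and the four short-separation
#' channels as scalp nuisance regressors. The six subject-level NC metrics
#' are the beta-weights averaged over long channels.
#'
#' The first and last `edge_trim_s` seconds of envelopes and hemoglobin
#' series are discarded (filter and Hilbert transients), and the first
#' `trim_s` seconds of the 1 Hz design are dropped (HRF convolution
#' transient).
#'
#' @param subject a `synthetic_subject`, or `NULL` when `eeg`/`intensity`/
#'   `age` are given directly.
#' @param eeg an [eeg_recording].
#' @param intensity an [optical_intensity].
#' @param age subject age in years.
#' @param bands named list of band edges (default [eeg_bands()]).
#' @param run_ica run automatic ICA artifact removal (default `FALSE`; enable
#'   for recordings with ocular/cardiac contamination).
#' @param edge_trim_s edge trim applied to envelopes and hemoglobin (s).
#' @param trim_s HRF transient trim of the design (s).
#' @param target_fs GLM rate (Hz).
#' @param kurtosis_threshold wavelet motion-correction threshold.
#' @param ica_seed seed for the ICA initialization.
#' @param min_row_factor,min_rows design-size requirements forwarded to
#'   [fit_glm_channel()] and [build_design()]; the defaults suit full-length
#'   recordings, short sweep windows relax them.
#' @return Object of class `nc_fit` with elements `metrics` (six NC values),
#'   `beta_hbo`, `beta_hbr` (per-channel weights), `variance_fractions`,
#'   `powers` (unimodal metrics), `age`, `n_rows` (GLM rows).
#' @export
nc_fit <- function(subject = NULL, eeg = NULL, intensity = NULL, age = NULL,
                   bands = eeg_bands(), run_ica = FALSE, edge_trim_s = 5,
                   trim_s = 30, target_fs = 1, kurtosis_threshold = 3.3,
                   ica_seed = 1, min_row_factor = 3, min_rows = 30) {
  if (!is.null(subject)) {
    stopifnot(inherits(subject, "synthetic_subject"))
    eeg <- subject$eeg; intensity <- subject$intensity; age <- subject$age
  }
  stopifnot(inherits(eeg, "eeg_recording"), inherits(intensity, "optical_intensity"))
  if (is.null(age)) stop_param("subject age required for the DPF model")

  ## EEG chain
  rec <- filter_eeg(eeg)
  if (run_ica) rec <- remove_artifacts_ica(rec, seed = ica_seed)$recording
  envs <- band_power_envelopes(rec, bands)

  ## fNIRS chain
  od <- intensity_to_od(intensity)
  od <- wavelet_motion_correct(od, kurtosis_threshold = kurtosis_threshold)
  od <- filter_od(od)
  hb <- od_to_hemoglobin(od, age)

  ## edge trim (both modalities, keeps time bases aligned)
  e_eeg <- round(edge_trim_s * rec$fs)
  e_nirs <- round(edge_trim_s * hb$fs)
  envs <- lapply(envs, function(e) {
    n <- ncol(e$envelope)
    e$envelope <- e$envelope[, (e_eeg + 1):(n - e_eeg), drop = FALSE]
    e
  })
  n_s <- ncol(hb$hbo)
  keep <- (e_nirs + 1):(n_s - e_nirs)
  hb$hbo <- hb$hbo[, keep, drop = FALSE]
  hb$hbr <- hb$hbr[, keep, drop = FALSE]

  globals <- lapply(envs, global_envelope_pca)
  hrf <- canonical_hrf(rec$fs)

  long <- which(hb$geometry$role == "long")
  band_columns <- hrf_band_columns(globals, target_fs, hrf)
  fit_chrom <- function(chrom) {
    des <- build_design(globals, hb, chromophore = chrom, target_fs = target_fs,
                        trim_s = trim_s, hrf = hrf, min_rows = min_rows,
                        band_columns = band_columns)
    Y <- if (chrom == "HbO") hb$hbo else hb$hbr
    betas <- t(vapply(long, function(ch) {
      y <- block_resample(Y[ch, ], hb$fs, target_fs)
      y <- y[(round(trim_s * target_fs) + 1):length(y)]
      y <- y[seq_len(nrow(des$X))]
      fit_glm_channel(des, y, min_row_factor = min_row_factor)$beta
    }, numeric(length(globals))))
    colnames(betas) <- des$band_cols
    rownames(betas) <- hb$geometry$channel[long]
    list(betas = betas, n_rows = nrow(des$X))
  }
  f_hbo <- fit_chrom("HbO")
  f_hbr <- fit_chrom("HbR")

  structure(list(
    metrics = subject_nc_metrics(f_hbo$betas, f_hbr$betas),
    beta_hbo = f_hbo$betas, beta_hbr = f_hbr$betas,
    variance_fractions = vapply(globals, function(g) g$variance_fraction, numeric(1)),
    powers = unimodal_powers(envs, hb),
    age = age,
    n_rows = f_hbo$n_rows),
    class = "nc_fit")
}

#' @export
print.nc_fit <- function(x, ...) {
  cat("Neurovascular coupling fit (standardized beta-weights, long-channel mean)\n")
  print(round(x$metrics, 4))
  cat(sprintf("PC1 variance fractions: %s\n",
              paste(sprintf("%s %.2f", names(x$variance_fractions),
                            x$variance_fractions), collapse = ", ")))
  invisible(x)
}

#' @export
coef.nc_fit <- function(object, ...) object$metrics

#' @export
summary.nc_fit <- function(object, ...) {
  res <- list(metrics = object$metrics,
              beta_sd = c(apply(object$beta_hbo, 2, stats::sd),
                          apply(object$beta_hbr, 2, stats::sd)),
              variance_fractions = object$variance_fractions,
              powers = object$powers)
  class(res) <- "summary.nc_fit"
  res
}

#' @export
print.summary.nc_fit <- function(x, ...) {
  cat("Six global NC metrics (band x chromophore):\n")
  print(round(x$metrics, 4))
  cat("Across-channel SD of beta-weights:\n")
  print(round(x$beta_sd, 4))
  cat("Unimodal power metrics:\n")
  print(signif(x$powers, 4))
  invisible(x)
}

#' Collect per-subject NC metrics into a cohort feature matrix
#'
#' @param fits list of `nc_fit` objects.
#' @return subjects x 6 numeric matrix of NC metrics.
#' @export
nc_metrics_table <- function(fits) {
  t(vapply(fits, function(f) f$metrics, numeric(6)))
}

#' Collect unimodal power metrics into feature matrices
#'
#' @param fits list of `nc_fit` objects.
#' @return List with `eeg` (subjects x 3 band powers) and `fnirs`
#'   (subjects x 2 hemoglobin powers) matrices.
#' @export
power_metrics_table <- function(fits) {
  P <- t(vapply(fits, function(f) f$powers, numeric(5)))
  list(eeg = P[, 1:3, drop = FALSE], fnirs = P[, 4:5, drop = FALSE])
}
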