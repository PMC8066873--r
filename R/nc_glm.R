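# Neurovascular coupling estimation: temporal PCA of band envelopes, design
# assembly with HRF convolution and short-channel nuisances, and per-channel
# standardized GLM fits.

#' Global band envelope by temporal PCA
#'
#' Z-scores each channel's envelope and extracts the first temporal principal
#' component across channels, i.e. a variance-weighted global envelope robust
#' to channel-wise noise. The component sign is fixed so the mean channel
#' loading is positive, making beta signs comparable across subjects.
#'
#' @param env a `band_envelope` (see [band_power_envelope()]) or a channels x
#'   samples matrix.
#' @return List of class `global_envelope`: `timecourse` (unit variance),
#'   `variance_fraction`, `loadings`, `fs`, `band`.
#' @export
global_envelope_pca <- function(env) {
  if (inherits(env, "band_envelope")) {
    X <- env$envelope; fs <- env$fs; band <- env$band
  } else {
    X <- as.matrix(env); fs <- NA_real_; band <- NULL
  }
  if (nrow(X) < 2) stop_param("need at least 2 channels")
  sds <- apply(X, 1, stats::sd)
  drop_ch <- which(sds == 0)
  if (length(drop_ch) == nrow(X)) stop_data("all channels have zero variance")
  if (length(drop_ch)) {
    warning("excluding ", length(drop_ch), " zero-variance channel(s) from PCA")
    X <- X[-drop_ch, , drop = FALSE]
    sds <- sds[-drop_ch]
  }
  Z <- (X - rowMeans(X)) / sds
  C <- tcrossprod(Z) / (ncol(Z) - 1)
  eg <- eigen(C, symmetric = TRUE)
  v <- eg$vectors[, 1]
  if (mean(v) < 0) v <- -v
  pc <- drop(crossprod(Z, v))
  structure(list(timecourse = pc / stats::sd(pc),
                 variance_fraction = eg$values[1] / sum(pmax(eg$values, 0)),
                 loadings = v, fs = fs, band = band),
            class = "global_envelope")
}

#' Assemble the NC design matrix
#'
#' Each global band envelope is convolved with the canonical HRF at its native
#' rate, resampled to `target_fs` by non-overlapping block averaging and
#' z-scored; the four short-separation hemoglobin series of the matching
#' chromophore are resampled and z-scored the same way; an intercept is
#' appended. The first `trim_s` seconds are discarded to remove the
#' convolution transient.
#'
#' @param globals list of three `global_envelope` objects (theta, alpha, beta).
#' @param short_hb matrix (short channels x samples) of the matching
#'   chromophore at the fNIRS rate, or a `hemoglobin` object plus `chromophore`.
#' @param fnirs_fs fNIRS sampling rate (needed when `short_hb` is a matrix).
#' @param chromophore `"HbO"` or `"HbR"` (when `short_hb` is a `hemoglobin`).
#' @param target_fs GLM rate in Hz (default 1).
#' @param trim_s transient trim in seconds (default 30).
#' @param hrf optional precomputed [canonical_hrf()] at the EEG rate.
#' @param min_rows minimal number of design rows after the trim (default 30,
#'   i.e. 30 s of overlap at 1 Hz; sweeps over short windows relax this).
#' @param band_columns optional precomputed HRF-convolved, resampled band
#'   predictor columns (as produced by [hrf_band_columns()]); avoids
#'   recomputing the convolutions when building the HbO and HbR designs from
#'   the same envelopes.
#' @return List of class `nc_design`: `X` (rows x columns with labelled
#'   predictors and intercept), `target_fs`, `band_cols`.
#' @export
build_design <- function(globals, short_hb, fnirs_fs = NULL,
                         chromophore = c("HbO", "HbR"), target_fs = 1,
                         trim_s = 30, hrf = NULL, min_rows = 30,
                         band_columns = NULL) {
  chromophore <- match.arg(chromophore)
  if (inherits(short_hb, "hemoglobin")) {
    sel <- short_hb$geometry$role == "short"
    if (!any(sel)) stop_data("no short-separation channels available")
    fnirs_fs <- short_hb$fs
    short_hb <- if (chromophore == "HbO") short_hb$hbo[sel, , drop = FALSE]
                else short_hb$hbr[sel, , drop = FALSE]
  }
  if (is.null(fnirs_fs)) stop_param("fnirs_fs required for matrix input")
  band_names <- vapply(seq_along(globals), function(i) {
    b <- globals[[i]]$band
    if (is.null(b)) paste0("band", i) else names(eeg_bands())[
      which(vapply(eeg_bands(), function(e) isTRUE(all.equal(e, b)), logical(1)))[1]]
  }, character(1))
  band_cols <- band_columns %||% hrf_band_columns(globals, target_fs, hrf)
  short_cols <- lapply(seq_len(nrow(short_hb)), function(i)
    block_resample(short_hb[i, ], fnirs_fs, target_fs))
  n <- min(vapply(c(band_cols, short_cols), length, integer(1)))
  skip <- round(trim_s * target_fs)
  if (n - skip < min_rows) stop_param("overlapping support too short after transient trim")
  rows <- (skip + 1):n
  cols <- c(band_cols, short_cols)
  labels <- c(band_names, paste0("short", seq_along(short_cols)))
  X <- vapply(cols, function(v) {
    v <- v[rows]
    s <- stats::sd(v)
    if (s == 0 || s < 1e-8 * abs(mean(v)))
      stop_data("degenerate (zero-variance) regressor in the design")
    (v - mean(v)) / s
  }, numeric(length(rows)))
  colnames(X) <- labels
  X <- cbind(X, intercept = 1)
  qr_x <- qr(X)
  if (qr_x$rank < ncol(X)) {
    dropped <- colnames(X)[qr_x$pivot[(qr_x$rank + 1):ncol(X)]]
    stop_numeric("design is rank deficient; collinear column(s): ",
                 paste(dropped, collapse = ", "))
  }
  structure(list(X = X, target_fs = target_fs, band_cols = band_names,
                 chromophore = chromophore),
            class = "nc_design")
}

#' HRF-convolved band predictor columns
#'
#' Convolves each global envelope with the canonical HRF at its native rate
#' and block-resamples to the GLM rate (the shared first stage of
#' [build_design()] for both chromophores).
#'
#' @param globals list of `global_envelope` objects.
#' @param target_fs GLM rate in Hz.
#' @param hrf optional precomputed [canonical_hrf()] at the envelope rate.
#' @return List of numeric predictor columns at `target_fs`.
#' @export
hrf_band_columns <- function(globals, target_fs = 1, hrf = NULL) {
  lapply(globals, function(g) {
    h <- hrf
    if (is.null(h) || !inherits(h, "hrf_kernel") || h$fs != g$fs)
      h <- canonical_hrf(g$fs)
    block_resample(convolve_causal(g$timecourse, h$kernel), g$fs, target_fs)
  })
}

#' Fit the NC general linear model for one long channel
#'
#' Ordinary least squares of a z-scored long-channel hemoglobin series on the
#' design. Because all non-intercept variables are z-scored, the band
#' coefficients are standardized regression weights (the per-channel NC
#' estimates).
#'
#' @param design an `nc_design`.
#' @param y response series at the design rate; z-scored internally unless its
#'   variance is already 1 within tolerance.
#' @param min_row_factor require `rows >= min_row_factor * columns` (default
#'   3; short sweep windows relax this to 1).
#' @return List: `beta` (named band coefficients), `coefficients` (all),
#'   `residual_sd`.
#' @export
fit_glm_channel <- function(design, y, min_row_factor = 3) {
  stopifnot(inherits(design, "nc_design"))
  X <- design$X
  if (length(y) != nrow(X)) stop_param("response length does not match design rows")
  if (nrow(X) < max(ncol(X) + 2, min_row_factor * ncol(X)))
    stop_param("too few rows for a stable fit")
  if (abs(stats::sd(y) - 1) > 1e-8 || abs(mean(y)) > 1e-8) y <- zscore(y)
  fit <- stats::lm.fit(X, y)
  if (fit$rank < ncol(X)) stop_numeric("singular normal equations in channel fit")
  cf <- fit$coefficients
  list(beta = cf[design$band_cols],
       coefficients = cf,
       residual_sd = stats::sd(fit$residuals))
}

#' Average per-channel beta-weights into subject NC metrics
#'
#' @param beta_hbo,beta_hbr long channels x bands matrices of standardized
#'   beta-weights (rows may be dropped by QC).
#' @return Named vector of six metrics, bands crossed with chromophores.
#' @export
subject_nc_metrics <- function(beta_hbo, beta_hbr) {
  if (is.null(dim(beta_hbo)) || nrow(beta_hbo) < 1 || nrow(beta_hbr) < 1)
    stop_data("at least one fitted long channel required per chromophore")
  m <- c(colMeans(beta_hbo), colMeans(beta_hbr))
  names(m) <- c(paste0(colnames(beta_hbo), ".HbO"), paste0(colnames(beta_hbr), ".HbR"))
  m
}

#' Unimodal power metrics
#'
#' Standalone (single-modality) summaries: the mean squared band envelope per
#' EEG band, and the per-channel standard deviation of the HbO and HbR series
#' averaged over long channels.
#'
#' @param envelopes named list of `band_envelope` objects.
#' @param hb a `hemoglobin` object.
#' @return Named vector: one power per band, `power.HbO`, `power.HbR`.
#' @export
unimodal_powers <- function(envelopes, hb) {
  if (length(envelopes) == 0) stop_param("no envelopes supplied")
  stopifnot(inherits(hb, "hemoglobin"))
  eeg_p <- vapply(envelopes, function(e) mean(e$envelope^2), numeric(1))
  names(eeg_p) <- paste0("power.", names(envelopes))
  long <- hb$geometry$role == "long"
  if (!any(long)) stop_data("no long channels for fNIRS power")
  c(eeg_p,
    power.HbO = mean(apply(hb$hbo[long, , drop = FALSE], 1, stats::sd)),
    power.HbR = mean(apply(hb$hbr[long, , drop = FALSE], 1, stats::sd)))
}
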