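# Seeded symmetric FastICA and automatic artifact-component rejection.
# No ICA implementation is available among the installed packages, so the
# fixed-point algorithm (tanh contrast, symmetric decorrelation) is
# implemented here directly.

fastica_decompose <- function(X, n_comp, seed = 1, max_iter = 200, tol = 1e-6) {
  n_ch <- nrow(X)
  Xc <- X - rowMeans(X)
  cv <- tcrossprod(Xc) / (ncol(Xc) - 1)
  eg <- eigen(cv, symmetric = TRUE)
  pos <- eg$values > max(eg$values) * 1e-10
  if (sum(pos) < n_comp)
    stop_numeric("rank-deficient data: only ", sum(pos), " non-degenerate directions for ",
                 n_comp, " requested components")
  K <- diag(1 / sqrt(eg$values[seq_len(n_comp)])) %*% t(eg$vectors[, seq_len(n_comp)])
  Z <- K %*% Xc                              # whitened: cov(Z) = I
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  W <- matrix(stats::rnorm(n_comp^2), n_comp)
  sym_decor <- function(W) {
    s <- svd(W)
    s$u %*% t(s$v)
  }
  W <- sym_decor(W)
  for (it in seq_len(max_iter)) {
    WX <- W %*% Z
    G <- tanh(WX)
    Gp <- 1 - G^2
    W1 <- sym_decor(G %*% t(Z) / ncol(Z) - diag(rowMeans(Gp)) %*% W)
    delta <- max(abs(abs(diag(W1 %*% t(W))) - 1))
    W <- W1
    if (delta < tol) break
  }
  S <- W %*% Z                               # components x samples
  A <- MASS_ginv(K) %*% t(W)                 # mixing: X ~ A %*% S (+ mean)
  list(S = S, A = A, means = rowMeans(X))
}

# Moore-Penrose pseudoinverse via SVD (kept local; MASS is not imported).
MASS_ginv <- function(M, tol = 1e-10) {
  s <- svd(M)
  keep <- s$d > max(s$d) * tol
  s$v[, keep, drop = FALSE] %*% (t(s$u[, keep, drop = FALSE]) / s$d[keep])
}

#' Remove stereotyped artifacts by independent component analysis
#'
#' Decomposes the recording with a seeded FastICA, flags components that look
#' like cardiac/ocular/muscle artifacts, zeroes them and reconstructs. Flagging
#' is fully automatic with two criteria: (a) excess kurtosis magnitude above
#' `kurt_threshold` (spiky, non-neural components) and (b) absolute correlation
#' above `corr_threshold` with a frontal low-frequency reference built as the
#' mean of the most anterior channels band-passed 1--4 Hz (ocular activity).
#'
#' @param rec a filtered [eeg_recording].
#' @param n_comp number of components (default `min(channels, 32)`).
#' @param kurt_threshold excess-kurtosis flagging threshold.
#' @param corr_threshold ocular-reference correlation threshold.
#' @param n_frontal number of anterior channels averaged into the reference
#'   (default one eighth of the montage, at least 2).
#' @param seed seed for the FastICA initialization.
#' @return List with the cleaned `recording`, integer `flagged` component
#'   indices and a per-component `report` data frame.
#' @export
remove_artifacts_ica <- function(rec, n_comp = NULL, kurt_threshold = 5,
                                 corr_threshold = 0.7, n_frontal = NULL, seed = 1) {
  stopifnot(inherits(rec, "eeg_recording"))
  n_ch <- nrow(rec$data)
  if (ncol(rec$data) < 3 * n_ch)
    stop_numeric("too few samples for a stable decomposition (need >= 3x channels)")
  n_comp <- n_comp %||% min(n_ch, 32L)
  n_frontal <- n_frontal %||% max(2L, n_ch %/% 8L)
  dec <- fastica_decompose(rec$data, n_comp, seed = seed)
  ref <- colMeans(rec$data[seq_len(n_frontal), , drop = FALSE])
  ref <- butter_filtfilt(ref, rec$fs, 1, 4, 2, "pass")
  kur <- apply(dec$S, 1, kurtosis_pearson) - 3
  cr <- apply(dec$S, 1, function(s) stats::cor(s, ref))
  flagged <- which(abs(kur) > kurt_threshold | abs(cr) > corr_threshold)
  report <- data.frame(component = seq_len(n_comp), excess_kurtosis = kur,
                       frontal_corr = cr,
                       flagged = seq_len(n_comp) %in% flagged)
  S <- dec$S
  if (length(flagged)) S[flagged, ] <- 0
  clean <- dec$A %*% S + dec$means
  list(recording = eeg_recording(clean, rec$fs, rec$channel_labels),
       flagged = flagged, report = report)
}
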