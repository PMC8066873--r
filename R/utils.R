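# Shared numerical helpers. All are internal.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_param <- function(...) {
  stop(structure(class = c("nvc_param_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_data <- function(...) {
  stop(structure(class = c("nvc_data_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

stop_numeric <- function(...) {
  stop(structure(class = c("nvc_numeric_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

#' @keywords internal
zscore <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) stop_numeric("cannot z-score a zero-variance series")
  (x - mean(x)) / s
}

# Pearson kurtosis (Gaussian -> 3).
kurtosis_pearson <- function(x) {
  x <- x - mean(x)
  m2 <- mean(x^2)
  if (m2 == 0) return(0)
  mean(x^4) / m2^2
}

# Magnitude of the analytic signal (FFT-based Hilbert transform).
analytic_envelope <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)
}

# Causal linear convolution of x with kernel k, truncated to length(x).
convolve_causal <- function(x, k) {
  n <- length(x)
  m <- length(k)
  nfft <- stats::nextn(n + m - 1, 2)
  X <- stats::fft(c(x, numeric(nfft - n)))
  K <- stats::fft(c(k, numeric(nfft - m)))
  y <- Re(stats::fft(X * K, inverse = TRUE) / nfft)
  y[seq_len(n)]
}

# Resample by averaging over non-overlapping blocks of 1/target_fs seconds.
# Works for non-integer fs ratios (e.g. 10.42 Hz -> 1 Hz): sample i (0-based)
# is assigned to block floor(i / fs * target_fs).
block_resample <- function(x, fs, target_fs = 1) {
  if (target_fs >= fs) stop_param("target rate must be below the native rate")
  idx <- floor((seq_along(x) - 1) / fs * target_fs)
  n_blocks <- floor(length(x) / fs * target_fs)
  keep <- idx < n_blocks
  idx <- idx[keep]
  as.numeric(rowsum(x[keep], idx)) / tabulate(idx + 1L)
}

# Deterministic child seeds for hierarchical simulation.
derive_seeds <- function(seed, n) {
  old <- get0(".Random.seed", envir = globalenv(), ifnotfound = NULL)
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Mean power spectral fraction of a series inside [f_lo, f_hi] (periodogram).
band_power_fraction <- function(x, fs, f_lo, f_hi) {
  n <- length(x)
  p <- Mod(stats::fft(x - mean(x))[seq_len(floor(n / 2) + 1)])^2
  f <- (seq_along(p) - 1) * fs / n
  sum(p[f >= f_lo & f <= f_hi]) / sum(p)
}
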