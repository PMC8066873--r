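# Independent oracles and shared small fixtures.

# Pseudoinverse least squares, independent of the package's lm.fit path.
pinv_solve <- function(X, y, tol = 1e-12) {
  s <- svd(X)
  keep <- s$d > max(s$d) * tol
  drop(s$v[, keep, drop = FALSE] %*%
         ((t(s$u[, keep, drop = FALSE]) %*% y) / s$d[keep]))
}

# Exhaustive concordant-pair AUC (ties count one half).
auc_by_enumeration <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Small memoized synthetic subject shared across test files.
local_cache <- new.env()

test_subject <- function(key = "default", ...) {
  if (is.null(local_cache[[key]])) {
    args <- list(...)
    if (is.null(args$spec))
      args$spec <- coupling_spec(beta = matrix(c(0.5, 0, 0, 0, 0, 0), 3, 2))
    args$duration_s <- args$duration_s %||% 60
    args$seed <- args$seed %||% 101
    args$n_channels <- args$n_channels %||% 8
    args$age <- args$age %||% 73
    local_cache[[key]] <- do.call(simulate_subject, args)
  }
  local_cache[[key]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Minimal optical_density wrapper around a single series.
od_from_series <- function(x, fs = 10.42) {
  structure(list(data = array(x, c(1, 1, length(x))), fs = fs,
                 wavelengths = 690, geometry = channel_geometry(1, 0)[1, ]),
            class = "optical_density")
}

# Band-limited hemodynamic-like carrier used in motion-correction tests.
hemodynamic_carrier <- function(n, fs = 10.42, seed = 3, sd_target = 0.01) {
  set.seed(seed)
  x <- stats::rnorm(n)
  b <- signal::butter(4, c(0.01, 0.4) / (fs / 2), "pass")
  x <- as.numeric(signal::filtfilt(b, x))
  x / sd(x) * sd_target
}
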