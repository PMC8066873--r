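# Canonical hemodynamic response function.

#' Canonical double-gamma hemodynamic response function
#'
#' Samples the standard two-gamma HRF: a positive response gamma (shape
#' `peak_shape`, unit rate, mode at `peak_shape - 1` s) minus an undershoot
#' gamma (shape `undershoot_shape`) scaled by `1/ratio`. The kernel starts at
#' zero, has a single positive main lobe peaking near 5 s, and is truncated
#' at `duration_s` then peak-normalized to 1.
#'
#' @param fs sampling rate of the kernel in Hz.
#' @param peak_shape,undershoot_shape gamma shape parameters (defaults 6, 16).
#' @param ratio peak-to-undershoot amplitude ratio (default 6).
#' @param duration_s kernel support in seconds (default 32).
#' @return List of class `hrf_kernel`: `kernel`, `fs`, `peak_time_s`.
#' @export
canonical_hrf <- function(fs, peak_shape = 6, undershoot_shape = 16,
                          ratio = 6, duration_s = 32) {
  if (fs <= 0) stop_param("fs must be positive")
  t <- seq(0, duration_s, by = 1 / fs)
  h <- stats::dgamma(t, shape = peak_shape, rate = 1) -
    stats::dgamma(t, shape = undershoot_shape, rate = 1) / ratio
  h <- h / max(h)
  structure(list(kernel = h, fs = fs, peak_time_s = t[which.max(h)]),
            class = "hrf_kernel")
}
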