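# Zero-lag Butterworth filtering used throughout both modality chains.

# Forward-backward IIR filtering of every column of a matrix (zero initial
# conditions, end-padding with 2 * filter length zeros before the forward
# pass). The inner loop lives in compiled code: multichannel filtering
# dominates the per-subject runtime otherwise.
filtfilt_cols <- function(b, a, M) {
  .filtfilt_cols_cpp(b, a, M)
}

# Design a Butterworth filter and apply it forward-backward (zero phase).
# x may be a vector or a channels x samples matrix (filtered along rows).
butter_filtfilt <- function(x, fs, low = NULL, high = NULL, order = 2,
                            type = c("pass", "low", "high", "stop")) {
  type <- match.arg(type)
  nyq <- fs / 2
  w <- switch(type,
    pass = , stop = {
      if (is.null(low) || is.null(high) || !(0 < low && low < high && high < nyq))
        stop_param("band edges must satisfy 0 < low < high < fs/2 (got ",
                   low, ", ", high, " at fs = ", fs, ")")
      c(low, high) / nyq
    },
    low = {
      if (is.null(high) || high <= 0 || high >= nyq) stop_param("invalid cut-off")
      high / nyq
    },
    high = {
      if (is.null(low) || low <= 0 || low >= nyq) stop_param("invalid cut-off")
      low / nyq
    })
  bf <- signal::butter(order, w, type = type)
  if (is.matrix(x)) .filtfilt_rows_cpp(bf$b, bf$a, x)
  else as.numeric(filtfilt_cols(bf$b, bf$a, matrix(x, ncol = 1)))
}
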