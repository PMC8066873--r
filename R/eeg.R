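# EEG containers, cleaning and band power envelope extraction.

#' Construct an EEG recording
#'
#' Container for a multichannel voltage recording. Channels are stored in
#' rows; the default montage labels channels `E1..En` in anterior-to-posterior
#' order, which is the convention the synthetic generator and the automatic
#' ocular-reference selection rely on.
#'
#' @param data channels x samples numeric matrix (microvolts).
#' @param fs sampling rate in Hz.
#' @param channel_labels optional character vector of montage labels.
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channel_labels = NULL) {
  data <- as.matrix(data)
  if (!is.numeric(data) || anyNA(data)) stop_data("EEG data must be numeric without NAs")
  if (nrow(data) < 4) stop_data("EEG recording needs at least 4 channels")
  if (!is.numeric(fs) || fs <= 0) stop_param("fs must be positive")
  if (is.null(channel_labels)) channel_labels <- paste0("E", seq_len(nrow(data)))
  structure(list(data = data, fs = fs, channel_labels = channel_labels),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("EEG recording: %d channels x %d samples at %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  invisible(x)
}

#' Canonical EEG frequency bands
#'
#' The three resting-state bands used for neurovascular coupling estimation.
#' Note the deliberate theta/alpha overlap (7.4--8.2 Hz) of the band scheme.
#'
#' @return Named list of `c(low, high)` band edges in Hz.
#' @export
eeg_bands <- function() {
  list(theta = c(3.5, 8.2), alpha = c(7.4, 13), beta = c(13, 30))
}

#' Broadband and notch filtering of raw EEG
#'
#' Zero-lag 2nd-order Butterworth band-pass between 1 and 80 Hz followed by a
#' zero-lag 2nd-order Butterworth band-stop notch around the 50 Hz mains line.
#'
#' @param rec an [eeg_recording].
#' @param low,high band-pass edges in Hz.
#' @param notch centre of the mains notch in Hz; half-width 2 Hz.
#' @param order filter order (applied forward-backward).
#' @return A filtered [eeg_recording].
#' @export
filter_eeg <- function(rec, low = 1, high = 80, notch = 50, order = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  if (rec$fs <= 2 * high) stop_param("sampling rate too low for a ", high, " Hz edge")
  y <- butter_filtfilt(rec$data, rec$fs, low, high, order, "pass")
  y <- butter_filtfilt(y, rec$fs, notch - 2, notch + 2, order, "stop")
  eeg_recording(y, rec$fs, rec$channel_labels)
}

#' Automatic channel quality control
#'
#' Flags channels that saturate (absolute amplitude above `amp_limit`) or are
#' flat (zero variance), replacing manual inspection of corrupted epochs.
#'
#' @param rec an [eeg_recording].
#' @param amp_limit rejection threshold in microvolts.
#' @return List with the retained `recording` and integer `rejected` indices.
#' @export
qc_eeg_channels <- function(rec, amp_limit = 500) {
  stopifnot(inherits(rec, "eeg_recording"))
  bad <- which(apply(rec$data, 1, function(v) max(abs(v)) > amp_limit || stats::sd(v) == 0))
  if (length(bad) == 0) return(list(recording = rec, rejected = integer(0)))
  if (nrow(rec$data) - length(bad) < 4) stop_data("QC left fewer than 4 usable channels")
  keep <- setdiff(seq_len(nrow(rec$data)), bad)
  list(recording = eeg_recording(rec$data[keep, , drop = FALSE], rec$fs,
                                 rec$channel_labels[keep]),
       rejected = bad)
}

# Squared magnitude response (i.e. the zero-phase forward-backward gain) of
# a digital Butterworth band-pass, evaluated on the FFT bin frequencies.
butter_gain2 <- function(n_samples, fs, band, order) {
  bf <- signal::butter(order, band / (fs / 2), type = "pass")
  w <- 2 * pi * (seq_len(n_samples) - 1) / n_samples
  z <- exp(-1i * w)
  horner <- function(cf) {
    acc <- rep(cf[1] + 0i, length(z))
    for (c_k in cf[-1]) acc <- acc * z + c_k
    acc
  }
  Mod(horner(bf$b) / horner(bf$a))^2
}

# Analytic-signal mask (doubles positive frequencies).
analytic_mask <- function(n) {
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1; h[2:((n + 1) / 2)] <- 2
  }
  h
}

#' Band power envelopes for several bands at once
#'
#' Shared-FFT implementation of [band_power_envelope()]: the recording is
#' Fourier-transformed once, each band applies the squared (zero-phase)
#' Butterworth magnitude response and the analytic-signal mask in the
#' frequency domain, and one inverse FFT per band yields the band-limited
#' analytic signal whose magnitude is the power envelope.
#'
#' @param rec an [eeg_recording] (already broadband-filtered).
#' @param bands named list of band edges (see [eeg_bands()]).
#' @param order band-pass order.
#' @return Named list of `band_envelope` objects.
#' @export
band_power_envelopes <- function(rec, bands = eeg_bands(), order = 2) {
  stopifnot(inherits(rec, "eeg_recording"))
  n <- ncol(rec$data)
  FT <- stats::mvfft(t(rec$data))
  u <- analytic_mask(n)
  out <- lapply(bands, function(band) {
    if (length(band) != 2 || band[1] <= 0 || band[2] <= band[1] ||
        band[2] >= rec$fs / 2)
      stop_param("band must lie strictly inside (0, fs/2)")
    g <- butter_gain2(n, rec$fs, band, order) * u
    env <- Mod(t(stats::mvfft(FT * g, inverse = TRUE) / n))
    structure(list(envelope = env, fs = rec$fs, band = band),
              class = "band_envelope")
  })
  names(out) <- names(bands)
  out
}

#' Band power envelope
#'
#' Zero-phase Butterworth band-pass to the requested band followed by the
#' magnitude of the per-channel analytic (Hilbert-transformed) signal.
#'
#' @param rec an [eeg_recording] (already broadband-filtered).
#' @param band `c(low, high)` in Hz, or a name from [eeg_bands()].
#' @param order band-pass order.
#' @return List with `envelope` (channels x samples, nonnegative), `fs`, `band`.
#' @export
band_power_envelope <- function(rec, band, order = 2) {
  if (is.character(band)) band <- eeg_bands()[[match.arg(band, names(eeg_bands()))]]
  band_power_envelopes(rec, list(band = band), order)[[1]]
}
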