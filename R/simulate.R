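# Synthetic EEG-fNIRS cohort generator with known ground-truth couplings.
# The forward model mirrors the analysis chain: band-limited neural latents
# are mixed into EEG channels; their HRF-convolved envelopes drive HbO/HbR
# in the long optical channels with signed, group-dependent couplings;
# systemic scalp oscillations are shared between long and short channels;
# hemoglobin is pushed forward through the same modified Beer-Lambert
# matrices the analysis inverts, and intensities are I_m * exp(-OD).

#' Coupling specification for synthetic subjects
#'
#' Houses the ground truth a generated subject is built from: the signed
#' band-to-chromophore coupling strengths and the nuisance/noise levels.
#'
#' @param beta 3 x 2 numeric matrix of signed coupling strengths, rows
#'   `theta`, `alpha`, `beta`, columns `HbO`, `HbR`; each entry scales a
#'   unit-variance HRF-convolved envelope drive in uM.
#' @param scalp_gain_long fraction of the systemic scalp signal leaking into
#'   long channels (short channels always carry it at unit gain).
#' @param noise_sd_eeg EEG sensor noise SD in microvolts.
#' @param noise_sd_od optical-density sensor noise SD (dimensionless).
#' @param motion_spike_rate motion spikes per minute added in OD space.
#' @return Object of class `coupling_spec`.
#' @export
coupling_spec <- function(beta = matrix(0, 3, 2), scalp_gain_long = 0.3,
                          noise_sd_eeg = 5, noise_sd_od = 0.01,
                          motion_spike_rate = 0) {
  beta <- as.matrix(beta)
  if (!all(dim(beta) == c(3, 2)) || !all(is.finite(beta)))
    stop_param("beta must be a finite 3 x 2 matrix (bands x chromophores)")
  dimnames(beta) <- list(c("theta", "alpha", "beta"), c("HbO", "HbR"))
  if (noise_sd_eeg < 0 || noise_sd_od < 0 || motion_spike_rate < 0)
    stop_param("noise SDs and motion rate must be nonnegative")
  structure(list(beta = beta, scalp_gain_long = scalp_gain_long,
                 noise_sd_eeg = noise_sd_eeg, noise_sd_od = noise_sd_od,
                 motion_spike_rate = motion_spike_rate),
            class = "coupling_spec")
}

#' Default group coupling specifications
#'
#' The reference study conditions for validation: healthy-control-like
#' subjects couple the theta envelope to HbO and the alpha envelope to HbR
#' (both +0.4), while AD-like subjects have all couplings at zero
#' (neurovascular un-coupling).
#'
#' @return List with elements `HC` and `AD`, each a [coupling_spec()].
#' @export
default_coupling_specs <- function() {
  b <- matrix(0, 3, 2)
  b[1, 1] <- 0.4  # theta -> HbO
  b[2, 2] <- 0.4  # alpha -> HbR
  list(HC = coupling_spec(beta = b), AD = coupling_spec())
}

#' Band-limited Gaussian latent activity
#'
#' Seeded white Gaussian noise band-pass filtered (zero-lag 4th-order
#' Butterworth) to the requested band and scaled to zero mean, unit variance.
#'
#' @param band_low_hz,band_high_hz band edges, `0 < low < high < fs/2`.
#' @param duration_s duration in seconds.
#' @param fs_hz sampling rate.
#' @param seed RNG seed (the output is bit-reproducible given the seed).
#' @return Numeric vector of `round(duration_s * fs_hz)` samples.
#' @export
band_limited_latent <- function(band_low_hz, band_high_hz, duration_s, fs_hz, seed) {
  if (!(0 < band_low_hz && band_low_hz < band_high_hz && band_high_hz < fs_hz / 2))
    stop_param("band edges must satisfy 0 < low < high < fs/2")
  set.seed(seed)
  x <- stats::rnorm(round(duration_s * fs_hz))
  x <- butter_filtfilt(x, fs_hz, band_low_hz, band_high_hz, 4, "pass")
  as.numeric(scale(x))
}

# Smooth, all-positive spatial lobe imitating volume conduction: a Gaussian
# bump at a random scalp position plus a positive floor.
volume_conduction_weights <- function(n_channels) {
  centre <- stats::runif(1, 1, n_channels)
  width <- n_channels / 6
  exp(-((seq_len(n_channels) - centre)^2) / (2 * width^2)) + 0.15
}

# Exponentially decaying steps of random sign injected in OD space.
motion_spikes <- function(n, fs, rate_per_min, tau_s = 1, amp_range = c(0.05, 0.15)) {
  out <- numeric(n)
  n_ev <- stats::rpois(1, rate_per_min * n / fs / 60)
  if (n_ev == 0) return(out)
  t0 <- sort(sample.int(n, n_ev, replace = TRUE))
  for (s in t0) {
    amp <- sample(c(-1, 1), 1) * stats::runif(1, amp_range[1], amp_range[2])
    idx <- s:n
    out[idx] <- out[idx] + amp * exp(-(idx - s) / (tau_s * fs))
  }
  out
}

#' Generate one synthetic EEG-fNIRS subject
#'
#' @param spec a [coupling_spec()] holding the ground truth.
#' @param age subject age in years (drives the DPF used in the forward model).
#' @param label group label, 1 (AD-like) or 0 (HC-like).
#' @param duration_s recording duration, at least 30 s (default 300 s).
#' @param seed RNG seed.
#' @param n_channels number of EEG channels (default 128).
#' @param fs_eeg,fs_fnirs sampling rates in Hz (defaults 250 and 10.42).
#' @param geometry optical probe geometry, see [channel_geometry()].
#' @param latent_amp_uV EEG amplitude of each unit-variance latent.
#' @param sys_hbo,sys_hbr systemic signal amplitude in HbO/HbR (uM).
#' @param hemo_band band limits of the generated hemodynamics (Hz); the
#'   default keeps the neural drives well inside the analysis band-pass.
#' @return Object of class `synthetic_subject`: `eeg`, `intensity`, `age`,
#'   `label`, `truth` (the coupling specification plus the injected drives and noise-free
#'   hemoglobin), `seed`.
#' @export
simulate_subject <- function(spec, age = 73, label = 0, duration_s = 300,
                             seed = 1, n_channels = 128, fs_eeg = 250,
                             fs_fnirs = 10.42, geometry = channel_geometry(),
                             latent_amp_uV = 20, sys_hbo = 1, sys_hbr = 0.4,
                             hemo_band = c(0.03, 0.2)) {
  stopifnot(inherits(spec, "coupling_spec"))
  if (duration_s <= 0) stop_param("duration must be positive")
  if (duration_s < 30) stop_param("duration must be at least 30 s")
  bands <- eeg_bands()
  lat_seeds <- derive_seeds(seed, 4L)
  latents <- vapply(seq_along(bands), function(i)
    band_limited_latent(bands[[i]][1], bands[[i]][2], duration_s, fs_eeg,
                        lat_seeds[i]),
    numeric(round(duration_s * fs_eeg)))

  set.seed(lat_seeds[4])
  ## EEG: smooth positive mixing + sensor noise
  W <- vapply(seq_along(bands), function(i) volume_conduction_weights(n_channels),
              numeric(n_channels))
  eeg_data <- W %*% t(latents) * latent_amp_uV +
    spec$noise_sd_eeg * matrix(stats::rnorm(n_channels * nrow(latents)),
                               n_channels)

  ## hemodynamic drives: HRF-convolved envelopes of the same latents
  n_od <- floor(duration_s * fs_fnirs)
  hrf <- canonical_hrf(fs_fnirs)
  drives <- vapply(seq_along(bands), function(i) {
    env <- analytic_envelope(latents[, i])
    env <- block_resample(env, fs_eeg, fs_fnirs)[seq_len(n_od)]
    d <- convolve_causal(env - mean(env), hrf$kernel)
    d <- butter_filtfilt(d, fs_fnirs, hemo_band[1], hemo_band[2], 4, "pass")
    as.numeric(scale(d))
  }, numeric(n_od))

  ## systemic scalp signal: slow (~0.1 Hz) oscillation + respiration band
  s1 <- butter_filtfilt(stats::rnorm(n_od), fs_fnirs, 0.08, 0.12, 4, "pass")
  s2 <- butter_filtfilt(stats::rnorm(n_od), fs_fnirs, 0.2, 0.3, 4, "pass")
  systemic <- as.numeric(scale(s1 / stats::sd(s1) + 0.5 * s2 / stats::sd(s2)))

  n_ch <- nrow(geometry)
  long <- geometry$role == "long"
  neural_hbo <- drop(drives %*% spec$beta[, "HbO"])
  neural_hbr <- drop(drives %*% spec$beta[, "HbR"])
  hbo <- matrix(rep(systemic * sys_hbo, each = n_ch), n_ch)
  hbr <- matrix(rep(systemic * sys_hbr, each = n_ch), n_ch)
  hbo[long, ] <- spec$scalp_gain_long * hbo[long, , drop = FALSE] +
    rep(neural_hbo, each = sum(long))
  hbr[long, ] <- spec$scalp_gain_long * hbr[long, , drop = FALSE] +
    rep(neural_hbr, each = sum(long))

  ## forward to optical densities and intensities
  od <- hemoglobin_to_od(hbo, hbr, geometry, age, fs_fnirs)
  for (ch in seq_len(n_ch))
    for (wl in 1:2) {
      v <- od$data[ch, wl, ]
      if (spec$motion_spike_rate > 0)
        v <- v + motion_spikes(n_od, fs_fnirs, spec$motion_spike_rate)
      od$data[ch, wl, ] <- v + spec$noise_sd_od * stats::rnorm(n_od)
    }
  i_m <- matrix(stats::runif(n_ch * 2, 500, 2000), n_ch)
  intens <- array(0, c(n_ch, 2, n_od))
  for (ch in seq_len(n_ch))
    for (wl in 1:2)
      intens[ch, wl, ] <- i_m[ch, wl] * exp(-od$data[ch, wl, ])

  structure(list(
    eeg = eeg_recording(eeg_data, fs_eeg),
    intensity = optical_intensity(intens, fs_fnirs, c(690, 830), geometry),
    age = age, label = as.integer(label), seed = seed,
    truth = list(spec = spec, drives = drives, hbo = hbo, hbr = hbr,
                 systemic = systemic)),
    class = "synthetic_subject")
}

#' @export
print.synthetic_subject <- function(x, ...) {
  cat(sprintf("Synthetic subject (label %d, age %.0f, seed %d)\n",
              x$label, x$age, x$seed))
  print(x$eeg); print(x$intensity)
  invisible(x)
}

#' Generate a synthetic two-group cohort
#'
#' Per-subject seeds are derived deterministically from the cohort seed; ages
#' are drawn from a normal distribution (mean 73, SD 7.5) truncated to
#' [50, 95].
#'
#' @param spec_ad,spec_hc group [coupling_spec()]s (defaults from
#'   [default_coupling_specs()]).
#' @param n_ad,n_hc group sizes (defaults 17 and 18).
#' @param duration_s recording duration in seconds.
#' @param seed cohort seed.
#' @param age_mean,age_sd age distribution parameters.
#' @param ... forwarded to [simulate_subject()] (e.g. `n_channels`).
#' @return Object of class `synthetic_cohort`: `subjects` (list), `labels`
#'   (1 = AD-like), `ages`, `seed`, `specs`.
#' @export
simulate_cohort <- function(spec_ad = default_coupling_specs()$AD,
                            spec_hc = default_coupling_specs()$HC,
                            n_ad = 17, n_hc = 18, duration_s = 300, seed = 1,
                            age_mean = 73, age_sd = 7.5, ...) {
  if (n_ad < 0 || n_hc < 0) stop_param("group sizes must be nonnegative")
  n <- n_ad + n_hc
  if (n == 0) stop_param("at least one subject required")
  seeds <- derive_seeds(seed, n + 1L)
  set.seed(seeds[n + 1L])
  ages <- stats::rnorm(5 * n, age_mean, age_sd)
  ages <- ages[ages >= 50 & ages <= 95][seq_len(n)]
  labels <- c(rep(1L, n_ad), rep(0L, n_hc))
  subjects <- lapply(seq_len(n), function(i)
    simulate_subject(if (labels[i] == 1L) spec_ad else spec_hc,
                     age = ages[i], label = labels[i],
                     duration_s = duration_s, seed = seeds[i], ...))
  structure(list(subjects = subjects, labels = labels, ages = ages,
                 seed = seed, specs = list(AD = spec_ad, HC = spec_hc)),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d subjects (%d AD-like, %d HC-like), seed %d\n",
              length(x$subjects), sum(x$labels == 1), sum(x$labels == 0), x$seed))
  invisible(x)
}
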