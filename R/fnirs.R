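# fNIRS containers and the optical-to-hemoglobin conversion chain.

#' Default EEG-fNIRS probe geometry
#'
#' 16 long-separation channels (35 mm source-detector distance, cortical
#' sensitivity) and 4 short-separation channels (15 mm, scalp sensitivity).
#'
#' @param n_long,n_short channel counts.
#' @param rho_long,rho_short interoptode distances in mm.
#' @return Data frame with `channel`, `rho` (mm) and `role` columns.
#' @export
channel_geometry <- function(n_long = 16, n_short = 4,
                             rho_long = 35, rho_short = 15) {
  if (rho_long <= 0 || rho_short <= 0) stop_param("interoptode distances must be positive")
  data.frame(channel = seq_len(n_long + n_short),
             rho = c(rep(rho_long, n_long), rep(rho_short, n_short)),
             role = c(rep("long", n_long), rep("short", n_short)))
}

#' Construct a dual-wavelength optical intensity recording
#'
#' @param data channels x wavelengths x samples positive array, wavelength
#'   order matching `wavelengths`.
#' @param fs sampling rate in Hz.
#' @param wavelengths wavelengths in nm (default 690 and 830).
#' @param geometry per-channel geometry, see [channel_geometry()].
#' @return An object of class `optical_intensity`.
#' @export
optical_intensity <- function(data, fs, wavelengths = c(690, 830),
                              geometry = channel_geometry()) {
  if (length(dim(data)) != 3) stop_data("intensity data must be channels x wavelengths x samples")
  if (dim(data)[2] != length(wavelengths)) stop_data("wavelength dimension mismatch")
  if (dim(data)[1] != nrow(geometry)) stop_data("geometry/channel mismatch")
  if (fs <= 0) stop_param("fs must be positive")
  bad <- which(apply(data, 1, function(m) any(m <= 0) || anyNA(m)))
  if (length(bad)) stop_data("nonpositive or missing intensity samples in channel(s) ",
                             paste(bad, collapse = ", "))
  structure(list(data = data, fs = fs, wavelengths = wavelengths, geometry = geometry),
            class = "optical_intensity")
}

#' @export
print.optical_intensity <- function(x, ...) {
  cat(sprintf("Optical intensities: %d channels (%d long, %d short) x {%s} nm x %d samples at %g Hz\n",
              dim(x$data)[1], sum(x$geometry$role == "long"),
              sum(x$geometry$role == "short"),
              paste(x$wavelengths, collapse = ", "), dim(x$data)[3], x$fs))
  invisible(x)
}

#' Intensity to optical density
#'
#' `OD(t) = -ln(I(t) / I_m)` per channel and wavelength, with `I_m` the mean
#' intensity over the (all-rest) recording, so `mean(OD) ~ 0` by construction.
#'
#' @param intensity an [optical_intensity].
#' @return An object of class `optical_density` with the same layout.
#' @export
intensity_to_od <- function(intensity) {
  stopifnot(inherits(intensity, "optical_intensity"))
  od <- intensity$data
  for (ch in seq_len(dim(od)[1]))
    for (wl in seq_len(dim(od)[2])) {
      v <- od[ch, wl, ]
      od[ch, wl, ] <- -log(v / mean(v))
    }
  structure(list(data = od, fs = intensity$fs, wavelengths = intensity$wavelengths,
                 geometry = intensity$geometry), class = "optical_density")
}

#' Hemodynamic band-pass of optical densities
#'
#' Zero-lag 4th-order Butterworth band-pass isolating the hemodynamic band.
#'
#' @param od an `optical_density`.
#' @param low,high cut-off frequencies in Hz (defaults 0.01 and 0.4).
#' @param order filter order.
#' @return Filtered `optical_density`.
#' @export
filter_od <- function(od, low = 0.01, high = 0.4, order = 4) {
  stopifnot(inherits(od, "optical_density"))
  if (od$fs <= 2 * high) stop_param("sampling rate too low for a ", high, " Hz edge")
  out <- od$data
  for (wl in seq_len(dim(out)[2])) {
    y <- butter_filtfilt(out[, wl, ], od$fs, low, high, order, "pass")
    # the high-pass removes DC analytically; subtract the small numerical
    # transient residual so stop-band rejection of offsets is exact
    out[, wl, ] <- y - rowMeans(y)
  }
  od$data <- out
  od
}

#' Molar extinction coefficients of hemoglobin
#'
#' Millimolar extinction coefficients of oxy- and deoxy-hemoglobin at the two
#' operating wavelengths, in 1/(mM x mm), compiled from the Zijlstra
#' whole-blood spectrophotometry tables (table version 1).
#'
#' @return 2 x 2 matrix, rows named by wavelength (nm), columns `HbO`, `HbR`.
#' @export
extinction_coefficients <- function() {
  matrix(c(0.0272, 0.2106,    # 690 nm
           0.1058, 0.0781),   # 830 nm
         nrow = 2, byrow = TRUE,
         dimnames = list(c("690", "830"), c("HbO", "HbR")))
}

#' Differential pathlength factor
#'
#' Evaluates the published general wavelength- and age-dependent DPF model
#' `DPF(lambda, A) = a + b A^c + d lambda^3 + e lambda^2 + f lambda` for
#' near-infrared wavelengths. DPF grows with age and is larger at 690 nm than
#' at 830 nm for the ages of interest.
#'
#' @param wavelength_nm wavelength in nm, within 650--900.
#' @param age_years subject age, within 18--100.
#' @return Dimensionless DPF (> 1).
#' @export
dpf <- function(wavelength_nm, age_years) {
  if (any(wavelength_nm < 650 | wavelength_nm > 900))
    stop_param("wavelength outside the 650-900 nm validity range")
  if (any(age_years < 18 | age_years > 100))
    stop_param("age outside the 18-100 y validity range")
  223.3 + 0.05624 * age_years^0.8493 - 5.723e-7 * wavelength_nm^3 +
    0.001245 * wavelength_nm^2 - 0.9025 * wavelength_nm
}

# The 2x2 modified Beer-Lambert system for one age: row = wavelength
# (830 first, then 690), column = chromophore (HbO, HbR); entries
# epsilon * DPF in 1/(mM mm) x dimensionless.
mbll_matrix <- function(age_years, extinction = extinction_coefficients()) {
  d830 <- dpf(830, age_years)
  d690 <- dpf(690, age_years)
  M <- rbind(extinction["830", ] * d830,
             extinction["690", ] * d690)
  rownames(M) <- c("830", "690")
  if (kappa(M) > 1e6)
    stop_numeric("extinction/DPF system is ill-conditioned; check the extinction table")
  M
}

#' Optical density to hemoglobin concentration changes
#'
#' Inverts the modified Beer-Lambert law per channel:
#' `[dHbO; dHbR] = (1/rho) M^-1 [OD_830; OD_690]` with `M` the 2x2 matrix of
#' extinction coefficient times DPF for each wavelength. With `rho` in mm and
#' extinction in 1/(mM mm) the result is in mM; it is returned in uM.
#'
#' @param od an `optical_density` holding both wavelengths.
#' @param age_years subject age (drives the DPF).
#' @param extinction extinction table, see [extinction_coefficients()].
#' @return Object of class `hemoglobin` with `hbo`, `hbr` (channels x samples,
#'   uM), `fs` and `geometry`.
#' @export
od_to_hemoglobin <- function(od, age_years, extinction = extinction_coefficients()) {
  stopifnot(inherits(od, "optical_density"))
  if (!all(c(690, 830) %in% od$wavelengths))
    stop_data("both 690 and 830 nm must be present")
  i690 <- which(od$wavelengths == 690)
  i830 <- which(od$wavelengths == 830)
  Minv <- solve(mbll_matrix(age_years, extinction))
  n_ch <- dim(od$data)[1]
  n_s <- dim(od$data)[3]
  hbo <- matrix(0, n_ch, n_s)
  hbr <- matrix(0, n_ch, n_s)
  for (ch in seq_len(n_ch)) {
    odm <- rbind(od$data[ch, i830, ], od$data[ch, i690, ])
    hb <- (Minv %*% odm) / od$geometry$rho[ch] * 1000   # mM -> uM
    hbo[ch, ] <- hb[1, ]
    hbr[ch, ] <- hb[2, ]
  }
  structure(list(hbo = hbo, hbr = hbr, fs = od$fs, geometry = od$geometry),
            class = "hemoglobin")
}

#' Forward modified Beer-Lambert model
#'
#' Maps hemoglobin concentration changes (uM) to optical densities at 690 and
#' 830 nm with the same extinction/DPF tables used by [od_to_hemoglobin()],
#' making exact round-trip checks possible.
#'
#' @param hbo,hbr channels x samples matrices in uM.
#' @param geometry per-channel geometry (`rho` in mm).
#' @param age_years subject age.
#' @param fs sampling rate in Hz.
#' @param extinction extinction table.
#' @return An `optical_density` (wavelength order 690, 830).
#' @export
hemoglobin_to_od <- function(hbo, hbr, geometry, age_years, fs,
                             extinction = extinction_coefficients()) {
  M <- mbll_matrix(age_years, extinction)
  n_ch <- nrow(hbo)
  n_s <- ncol(hbo)
  od <- array(0, c(n_ch, 2, n_s))
  for (ch in seq_len(n_ch)) {
    v <- M %*% rbind(hbo[ch, ], hbr[ch, ]) * geometry$rho[ch] / 1000  # uM -> mM
    od[ch, 1, ] <- v["690", ]
    od[ch, 2, ] <- v["830", ]
  }
  structure(list(data = od, fs = fs, wavelengths = c(690, 830), geometry = geometry),
            class = "optical_density")
}

#' Automatic optical-channel quality control
#'
#' Flags channels whose post-filter OD standard deviation exceeds a ceiling,
#' replacing manual inspection of the filtered optical densities.
#'
#' @param od a filtered `optical_density`.
#' @param sd_ceiling maximal acceptable OD standard deviation.
#' @return Integer vector of flagged channel indices.
#' @export
qc_od_channels <- function(od, sd_ceiling = 0.5) {
  stopifnot(inherits(od, "optical_density"))
  which(apply(od$data, 1, function(m) max(apply(m, 1, stats::sd))) > sd_ceiling)
}
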