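# Plain-text interchange bundle for subjects and cohorts. A bundle is a
# directory holding a JSON manifest (rates, metadata, ground truth, seeds)
# and CSV arrays: eeg.csv (samples x channels), intensity_<wl>.csv per
# wavelength (samples x channels) and geometry.csv.

BUNDLE_VERSION <- "1"

#' Write a subject to an interchange bundle
#'
#' @param subject a `synthetic_subject` (or a list with `eeg`, `intensity`,
#'   `age`, `label`).
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_subject_bundle <- function(subject, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  eeg <- subject$eeg
  intens <- subject$intensity
  manifest <- list(bundle_version = BUNDLE_VERSION,
                   fs_eeg = eeg$fs, fs_fnirs = intens$fs,
                   wavelengths = intens$wavelengths,
                   channel_labels = eeg$channel_labels,
                   age = subject$age, label = subject$label,
                   seed = subject$seed %||% NA)
  if (!is.null(subject$truth))
    manifest$truth_beta <- as.data.frame(subject$truth$spec$beta)
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  utils::write.csv(t(eeg$data), file.path(path, "eeg.csv"), row.names = FALSE)
  for (i in seq_along(intens$wavelengths))
    utils::write.csv(t(intens$data[, i, ]),
                     file.path(path, sprintf("intensity_%d.csv", intens$wavelengths[i])),
                     row.names = FALSE)
  utils::write.csv(intens$geometry, file.path(path, "geometry.csv"),
                   row.names = FALSE)
  invisible(path)
}

#' Read a subject bundle
#'
#' @param path bundle directory written by [write_subject_bundle()].
#' @return List of class `synthetic_subject` (ground-truth timecourses are
#'   not stored in bundles; `truth` carries the coupling matrix only).
#' @export
read_subject_bundle <- function(path) {
  man_file <- file.path(path, "manifest.json")
  if (!file.exists(man_file)) stop_data("no manifest.json under ", path)
  man <- jsonlite::read_json(man_file, simplifyVector = TRUE)
  loaded <- load_subject(file.path(path, "eeg.csv"), path,
                         meta = list(fs_eeg = man$fs_eeg, fs_fnirs = man$fs_fnirs,
                                     wavelengths = man$wavelengths,
                                     channel_labels = man$channel_labels))
  truth <- NULL
  if (!is.null(man$truth_beta))
    truth <- list(spec = coupling_spec(beta = as.matrix(man$truth_beta)))
  structure(list(eeg = loaded$eeg, intensity = loaded$intensity,
                 age = man$age, label = man$label, seed = man$seed,
                 truth = truth),
            class = "synthetic_subject")
}

#' Load one subject from EEG and fNIRS files
#'
#' Reads the EEG array (CSV, samples x channels) and the optical intensities
#' (directory with one `intensity_<wavelength>.csv` per wavelength plus
#' `geometry.csv`), validates them and trims both modalities to their common
#' duration. Durations differing by more than `max_mismatch_s` are rejected.
#'
#' @param eeg_path CSV file of EEG samples x channels.
#' @param fnirs_path directory holding the intensity and geometry CSVs.
#' @param meta list with at least `fs_eeg` and `fs_fnirs`; optional
#'   `wavelengths` (default `c(690, 830)`) and `channel_labels`.
#' @param max_mismatch_s largest tolerated duration mismatch in seconds.
#' @return List with `eeg` ([eeg_recording]) and `intensity`
#'   ([optical_intensity]), trimmed to common support.
#' @export
load_subject <- function(eeg_path, fnirs_path, meta, max_mismatch_s = 15) {
  if (is.null(meta$fs_eeg) || is.null(meta$fs_fnirs))
    stop_param("meta must provide fs_eeg and fs_fnirs")
  wavelengths <- meta$wavelengths %||% c(690, 830)
  if (!file.exists(eeg_path)) stop_data("EEG file not found: ", eeg_path)
  eeg_mat <- t(as.matrix(utils::read.csv(eeg_path)))
  geom_file <- file.path(fnirs_path, "geometry.csv")
  if (!file.exists(geom_file)) stop_data("geometry.csv not found under ", fnirs_path)
  geometry <- utils::read.csv(geom_file)
  wl_data <- lapply(wavelengths, function(wl) {
    f <- file.path(fnirs_path, sprintf("intensity_%d.csv", wl))
    if (!file.exists(f)) stop_data("missing wavelength ", wl, " nm intensity file")
    t(as.matrix(utils::read.csv(f)))
  })
  n_od <- unique(vapply(wl_data, ncol, integer(1)))
  if (length(n_od) > 1) stop_data("wavelength files disagree in length")
  dur_eeg <- ncol(eeg_mat) / meta$fs_eeg
  dur_od <- n_od / meta$fs_fnirs
  if (abs(dur_eeg - dur_od) > max_mismatch_s)
    stop_data(sprintf("duration mismatch: EEG %.1f s vs fNIRS %.1f s", dur_eeg, dur_od))
  if (abs(dur_eeg - dur_od) <= 1 / meta$fs_fnirs) {
    # equal within one optical sample: keep both untouched
    intens <- array(0, c(nrow(wl_data[[1]]), length(wavelengths), n_od))
    for (i in seq_along(wl_data)) intens[, i, ] <- wl_data[[i]]
    return(list(eeg = eeg_recording(eeg_mat, meta$fs_eeg,
                                    unlist(meta$channel_labels) %||% NULL),
                intensity = optical_intensity(intens, meta$fs_fnirs,
                                              wavelengths, geometry)))
  }
  dur <- min(dur_eeg, dur_od)
  message(sprintf("trimming both modalities to the common %.1f s", dur))
  eeg_mat <- eeg_mat[, seq_len(round(dur * meta$fs_eeg)), drop = FALSE]
  n_keep <- floor(dur * meta$fs_fnirs)
  intens <- array(0, c(nrow(wl_data[[1]]), length(wavelengths), n_keep))
  for (i in seq_along(wl_data)) intens[, i, ] <- wl_data[[i]][, seq_len(n_keep)]
  list(eeg = eeg_recording(eeg_mat, meta$fs_eeg,
                           unlist(meta$channel_labels) %||% NULL),
       intensity = optical_intensity(intens, meta$fs_fnirs, wavelengths, geometry))
}

#' Write a cohort to a bundle directory
#'
#' One sub-bundle per subject plus a cohort manifest recording seeds, labels
#' and the group coupling specifications.
#'
#' @param cohort a `synthetic_cohort`.
#' @param path directory to create.
#' @return `path`, invisibly.
#' @export
write_cohort_bundle <- function(cohort, path) {
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  for (i in seq_along(cohort$subjects))
    write_subject_bundle(cohort$subjects[[i]],
                         file.path(path, sprintf("subject_%02d", i)))
  manifest <- list(bundle_version = BUNDLE_VERSION, seed = cohort$seed,
                   labels = cohort$labels, ages = cohort$ages,
                   spec_AD = as.data.frame(cohort$specs$AD$beta),
                   spec_HC = as.data.frame(cohort$specs$HC$beta))
  jsonlite::write_json(manifest, file.path(path, "cohort.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}
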