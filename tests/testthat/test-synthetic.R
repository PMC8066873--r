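# Synthetic cohort generator: seeded determinism, forward/inverse
# consistency and coupling recovery.

test_that("band-limited latents are in-band, unit variance and seeded", {
  x <- band_limited_latent(7.4, 13, 60, 250, seed = 1)
  expect_equal(sd(x), 1, tolerance = 1e-10)
  expect_equal(mean(x), 0, tolerance = 1e-10)
  expect_gt(nvcoupling:::band_power_fraction(x, 250, 7.4, 13), 0.95)
  expect_identical(x, band_limited_latent(7.4, 13, 60, 250, seed = 1))
  expect_false(identical(x, band_limited_latent(7.4, 13, 60, 250, seed = 2)))
  expect_error(band_limited_latent(13, 7.4, 60, 250, 1),
               class = "nvc_param_error")
})

test_that("generated subjects are well-formed and bit-reproducible", {
  sub <- test_subject()
  expect_s3_class(sub$eeg, "eeg_recording")
  expect_s3_class(sub$intensity, "optical_intensity")
  dur_eeg <- ncol(sub$eeg$data) / sub$eeg$fs
  dur_od <- dim(sub$intensity$data)[3] / sub$intensity$fs
  expect_lt(abs(dur_eeg - dur_od), 1 / sub$intensity$fs)
  expect_true(all(sub$intensity$data > 0))
  sub2 <- simulate_subject(sub$truth$spec, age = 73, label = 0,
                           duration_s = 60, seed = 101, n_channels = 8)
  expect_identical(sub$eeg$data, sub2$eeg$data)
  expect_identical(sub$intensity$data, sub2$intensity$data)
  expect_error(simulate_subject(coupling_spec(), duration_s = -5, seed = 1),
               class = "nvc_param_error")
  expect_error(coupling_spec(noise_sd_od = -1), class = "nvc_param_error")
})

test_that("noise-free forward model is inverted by the fNIRS chain", {
  spec0 <- coupling_spec(beta = matrix(c(0.5, 0, 0, 0, 0.3, 0), 3, 2),
                         scalp_gain_long = 0, noise_sd_eeg = 0,
                         noise_sd_od = 0)
  sub <- simulate_subject(spec0, age = 73, label = 0, duration_s = 120,
                          seed = 7, n_channels = 8)
  hb <- od_to_hemoglobin(filter_od(wavelet_motion_correct(
    intensity_to_od(sub$intensity))), sub$age)
  interior <- 150:(ncol(hb$hbo) - 150)
  relerr <- function(a, b) sqrt(mean((a - b)^2)) / sqrt(mean(b^2))
  expect_lt(relerr(hb$hbo[1, interior], sub$truth$hbo[1, interior]), 0.01)
  expect_lt(relerr(hb$hbr[1, interior], sub$truth$hbr[1, interior]), 0.01)
})

test_that("zero-coupling subjects yield near-zero metrics and a planted
           theta-HbO coupling dominates the other five", {
  sub0 <- test_subject("null_subject", spec = coupling_spec(),
                       duration_s = 90, seed = 33, n_channels = 8)
  f0 <- nc_fit(sub0)
  se <- c(apply(f0$beta_hbo, 2, sd), apply(f0$beta_hbr, 2, sd)) /
    sqrt(nrow(f0$beta_hbo))
  expect_true(all(abs(f0$metrics) < pmax(2 * se, 0.15)))
  sub1 <- test_subject("theta_subject",
                       spec = coupling_spec(
                         beta = matrix(c(0.5, 0, 0, 0, 0, 0), 3, 2),
                         noise_sd_eeg = 2, noise_sd_od = 0.003),
                       duration_s = 90, seed = 34, n_channels = 8)
  f1 <- nc_fit(sub1)
  expect_identical(names(which.max(abs(f1$metrics))), "theta.HbO")
  expect_gt(f1$metrics["theta.HbO"], max(abs(f1$metrics[-1])) + 0.1)
})

test_that("motion spikes create the outliers the kurtosis filter targets", {
  spec_m <- coupling_spec(motion_spike_rate = 6)
  sub_m <- simulate_subject(spec_m, 73, 0, 120, seed = 55, n_channels = 8)
  spec_0 <- coupling_spec(motion_spike_rate = 0)
  sub_0 <- simulate_subject(spec_0, 73, 0, 120, seed = 55, n_channels = 8)
  level_kurt <- function(sub) {
    od <- intensity_to_od(sub$intensity)
    w <- nvcoupling:::dwt_periodized(od$data[1, 1, ], 6)
    max(vapply(w$d, nvcoupling:::kurtosis_pearson, numeric(1)))
  }
  expect_gt(level_kurt(sub_m), 3.3)
  expect_gt(level_kurt(sub_m), level_kurt(sub_0))
  # without spikes the OD derivative stays at the hemodynamic+noise scale
  d0 <- max(abs(diff(intensity_to_od(sub_0$intensity)$data[1, 1, ])))
  dm <- max(abs(diff(intensity_to_od(sub_m$intensity)$data[1, 1, ])))
  expect_gt(dm, 2 * d0)
})

test_that("mean estimated coupling increases monotonically with the truth", {
  betas <- c(0, 0.2, 0.4, 0.6)
  means <- vapply(betas, function(b) {
    spec <- coupling_spec(beta = matrix(c(b, 0, 0, 0, 0, 0), 3, 2))
    mean(vapply(1:10, function(r) {
      sub <- simulate_subject(spec, 73, 0, 120, seed = 700 + r, n_channels = 8)
      nc_fit(sub)$metrics["theta.HbO"]
    }, numeric(1)))
  }, numeric(1))
  expect_true(all(diff(means) > 0))
})

test_that("cohorts have the requested composition and are reproducible", {
  specs <- default_coupling_specs()
  coh <- simulate_cohort(specs$AD, specs$HC, n_ad = 3, n_hc = 4,
                         duration_s = 30, seed = 9, n_channels = 8)
  expect_length(coh$subjects, 7)
  expect_identical(sum(coh$labels), 3L)
  expect_true(all(coh$ages >= 50))
  coh2 <- simulate_cohort(specs$AD, specs$HC, n_ad = 3, n_hc = 4,
                          duration_s = 30, seed = 9, n_channels = 8)
  expect_identical(coh$subjects[[5]]$eeg$data, coh2$subjects[[5]]$eeg$data)
  expect_error(simulate_cohort(n_ad = 0, n_hc = 0), class = "nvc_param_error")
})
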