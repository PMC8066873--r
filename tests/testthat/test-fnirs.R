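# Optical chain: OD conversion, hemodynamic filtering, DPF and the modified
# Beer-Lambert inversion.

make_intensity <- function(data, fs = 10.42, geometry = channel_geometry(2, 1)) {
  optical_intensity(data, fs, c(690, 830), geometry)
}

test_that("optical density follows -ln(I/I_m) closed forms", {
  n <- 64
  base <- array(1000, c(3, 2, n))
  od <- intensity_to_od(make_intensity(base))
  expect_equal(max(abs(od$data)), 0)
  # single-sample excursions against an otherwise constant baseline:
  # I close to I_m keeps the mean near the constant level
  x <- array(1000, c(3, 2, 1000))
  x[1, 1, 5] <- 1000 * exp(-1)
  x[2, 2, 7] <- 500
  od2 <- intensity_to_od(make_intensity(x))
  im1 <- mean(x[1, 1, ]); im2 <- mean(x[2, 2, ])
  expect_equal(od2$data[1, 1, 5], -log(x[1, 1, 5] / im1), tolerance = 1e-12)
  expect_equal(od2$data[2, 2, 7], log(im2 / 500), tolerance = 1e-12)
  # near-zero mean by construction (exact only to first order in the
  # excursion, since the log is nonlinear)
  expect_lt(abs(mean(od2$data[1, 1, ])), 1e-3)
  bad <- x; bad[2, 1, 3] <- -1
  err <- tryCatch(make_intensity(bad), error = function(e) conditionMessage(e))
  expect_match(err, "2")
})

test_that("hemodynamic band-pass keeps 0.1 Hz, rejects DC and 1 Hz", {
  fs <- 10.42
  t <- seq(0, 600, by = 1 / fs); n <- length(t)
  arr <- array(0, c(2, 2, n))
  arr[1, 1, ] <- sin(2 * pi * 0.1 * t)
  arr[1, 2, ] <- sin(2 * pi * 1 * t)
  arr[2, 1, ] <- 5                      # DC
  arr[2, 2, ] <- sin(2 * pi * 0.1 * t)
  od <- structure(list(data = arr, fs = fs, wavelengths = c(690, 830),
                       geometry = channel_geometry(2, 0)),
                  class = "optical_density")
  f <- filter_od(od)
  cen <- round(n * 0.3):round(n * 0.7)
  expect_equal(max(abs(f$data[1, 1, cen])), 1, tolerance = 0.05)
  expect_lt(max(abs(f$data[1, 2, cen])), 0.05)
  expect_lt(abs(mean(f$data[2, 1, ])), 1e-6 * 5)
  slow <- od; slow$fs <- 0.7
  expect_error(filter_od(slow), class = "nvc_param_error")
})

test_that("DPF grows with age, is larger at 690 nm, and validates inputs", {
  expect_gt(dpf(830, 80), dpf(830, 20))
  expect_gt(dpf(690, 70), dpf(830, 70))
  expect_gt(dpf(830, 20), 1)
  expect_error(dpf(500, 70), class = "nvc_param_error")
  expect_error(dpf(830, 110), class = "nvc_param_error")
})

test_that("Beer-Lambert inversion is exact, linear and scales as 1/rho", {
  geom <- channel_geometry(2, 1)
  hbo <- matrix(rep(c(1, -0.4, 0.25), each = 40), 3, 40, byrow = TRUE)
  hbr <- matrix(rep(c(-0.25, 0.1, 0.8), each = 40), 3, 40, byrow = TRUE)
  od <- hemoglobin_to_od(hbo, hbr, geom, 73, 10.42)
  hb <- od_to_hemoglobin(od, 73)
  expect_lt(max(abs(hb$hbo - hbo)), 1e-9)
  expect_lt(max(abs(hb$hbr - hbr)), 1e-9)

  # zero maps to zero
  od0 <- od; od0$data[] <- 0
  hb0 <- od_to_hemoglobin(od0, 73)
  expect_equal(max(abs(hb0$hbo)), 0)

  # superposition to machine precision
  od2 <- od; od2$data <- od$data * 2
  hb2 <- od_to_hemoglobin(od2, 73)
  expect_equal(hb2$hbo, 2 * hb$hbo, tolerance = 1e-12)

  # doubling rho halves the recovered concentrations for the same OD
  geom2 <- geom; geom2$rho <- geom$rho * 2
  odr <- od; odr$geometry <- geom2
  hbr2 <- od_to_hemoglobin(odr, 73)
  expect_equal(hbr2$hbo, hb$hbo / 2, tolerance = 1e-12)

  # missing wavelength
  od1 <- od; od1$wavelengths <- c(690, 700)
  expect_error(od_to_hemoglobin(od1, 73), class = "nvc_data_error")
})

test_that("OD channel QC flags only channels above the SD ceiling", {
  n <- 200
  arr <- array(rnorm(2 * 2 * n, sd = 0.01), c(2, 2, n))
  arr[2, 1, ] <- rnorm(n, sd = 2)
  od <- structure(list(data = arr, fs = 10.42, wavelengths = c(690, 830),
                       geometry = channel_geometry(2, 0)),
                  class = "optical_density")
  expect_identical(qc_od_channels(od), 2L)
})
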