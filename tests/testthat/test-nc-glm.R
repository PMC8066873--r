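# Temporal PCA, HRF, design assembly and the standardized GLM.

test_that("temporal PCA recovers planted global structure", {
  # rank-1 input: variance fraction 1, PC1 proportional to the common series
  s <- sin(seq(0, 20, length.out = 2000)) + 2
  X <- matrix(rep(s, 5), 5, byrow = TRUE) * c(1, 2, 3, 4, 5)
  g <- global_envelope_pca(X)
  expect_equal(g$variance_fraction, 1, tolerance = 1e-10)
  expect_equal(abs(cor(g$timecourse, s)), 1, tolerance = 1e-10)
  # two orthogonal equal-variance channels split the variance evenly
  t2 <- seq_len(4000)
  X2 <- rbind(sin(2 * pi * t2 / 100), cos(2 * pi * t2 / 100))
  expect_equal(global_envelope_pca(X2)$variance_fraction, 0.5,
               tolerance = 1e-3)
  # planted single factor with positive weights and 10% noise
  set.seed(8)
  latent <- as.numeric(scale(cumsum(rnorm(3000))))
  W <- runif(128, 0.5, 1.5)
  Xp <- outer(W, latent) + matrix(rnorm(128 * 3000, sd = 0.1 * sd(latent)), 128)
  gp <- global_envelope_pca(Xp)
  expect_gt(abs(cor(gp$timecourse, latent)), 0.99)
  expect_gt(mean(gp$loadings), 0)   # sign convention
  # degenerate inputs
  Xz <- Xp; Xz[3, ] <- 5
  expect_warning(global_envelope_pca(Xz), "zero-variance")
  expect_error(global_envelope_pca(matrix(1, 4, 100)), class = "nvc_data_error")
})

test_that("the canonical HRF has the double-gamma shape", {
  h <- canonical_hrf(10)
  expect_equal(h$kernel[1], 0)
  expect_equal(max(h$kernel), 1)
  expect_gte(h$peak_time_s, 4.5)
  expect_lte(h$peak_time_s, 6.5)
  # convolution with a unit impulse reproduces the kernel
  imp <- c(1, numeric(499))
  expect_equal(nvcoupling:::convolve_causal(imp, h$kernel)[seq_along(h$kernel)],
               h$kernel, tolerance = 1e-12)
})

make_globals <- function(n_s = 200, fs = 25, seed = 1) {
  set.seed(seed)
  lapply(eeg_bands(), function(b)
    structure(list(timecourse = rnorm(n_s * fs), fs = fs,
                   variance_fraction = 0.6, band = b),
              class = "global_envelope"))
}

make_short_hb <- function(n_short = 4, n_s = 200, fs = 10.42, seed = 2) {
  set.seed(seed)
  matrix(rnorm(n_short * floor(n_s * fs)), n_short)
}

test_that("design assembly z-scores, labels and rank-checks the columns", {
  globals <- make_globals()
  short <- make_short_hb()
  des <- build_design(globals, short, fnirs_fs = 10.42)
  expect_identical(colnames(des$X),
                   c("theta", "alpha", "beta", paste0("short", 1:4), "intercept"))
  expect_true(all(abs(colMeans(des$X[, 1:7])) < 1e-10))
  expect_true(all(abs(apply(des$X[, 1:7], 2, sd) - 1) < 1e-10))
  expect_true(all(des$X[, 8] == 1))
  # HRF low-pass property: band columns concentrate below 0.2 Hz
  frac <- nvcoupling:::band_power_fraction(des$X[, 1], 1, 0, 0.2)
  expect_gt(frac, 0.9)
  # duplicated short channel -> collinearity error naming the column
  short_dup <- short; short_dup[2, ] <- short_dup[1, ]
  err <- tryCatch(build_design(globals, short_dup, fnirs_fs = 10.42),
                  error = function(e) conditionMessage(e))
  expect_match(err, "short")
  # constant envelope: once the trim clears the 32 s kernel support its
  # convolution is exactly constant -> degenerate regressor
  g0 <- globals; g0[[2]]$timecourse <- rep(1, length(g0[[2]]$timecourse))
  expect_error(build_design(g0, short, fnirs_fs = 10.42, trim_s = 35),
               class = "nvc_data_error")
})

scale_design <- function(X) {
  Z <- apply(X[, 1:7], 2, function(v) as.numeric(scale(v)))
  colnames(Z) <- colnames(X)[1:7]
  cbind(Z, intercept = 1)
}

test_that("channel GLM matches the pseudoinverse oracle and null bounds", {
  globals <- make_globals(seed = 3)
  des <- build_design(globals, make_short_hb(seed = 4), fnirs_fs = 10.42)
  # perfect fit: response equals the theta column
  fit <- fit_glm_channel(des, des$X[, "theta"])
  expect_equal(unname(fit$beta), c(1, 0, 0), tolerance = 1e-10)
  # independent white-noise response: every |beta| < 3/sqrt(n)
  set.seed(9)
  fit0 <- fit_glm_channel(des, rnorm(nrow(des$X)))
  expect_true(all(abs(fit0$beta) < 3 / sqrt(nrow(des$X))))
  # random instances against an independent pseudoinverse solve
  set.seed(10)
  for (r in 1:20) {
    X <- cbind(matrix(rnorm(50 * 7), 50), 1)
    colnames(X) <- c("theta", "alpha", "beta", paste0("short", 1:4), "intercept")
    d <- structure(list(X = scale_design(X), target_fs = 1,
                        band_cols = c("theta", "alpha", "beta"),
                        chromophore = "HbO"), class = "nc_design")
    y <- rnorm(50)
    got <- fit_glm_channel(d, y)$coefficients
    expect_lt(max(abs(got - pinv_solve(d$X, as.numeric(scale(y))))), 1e-8)
  }
  expect_error(fit_glm_channel(des, rnorm(10)), class = "nvc_param_error")
})

test_that("subject metrics average the long-channel weights", {
  b <- matrix(0.3, 16, 3, dimnames = list(NULL, c("theta", "alpha", "beta")))
  m <- subject_nc_metrics(b, b)
  expect_length(m, 6)
  expect_true(all(m == 0.3))
  b2 <- matrix(c(0.2, 0.4), 2, 3, dimnames = list(NULL, colnames(b)))
  expect_equal(unname(subject_nc_metrics(b2, b2)["theta.HbO"]), 0.3)
  # QC-excluded channel: mean over the surviving subset
  expect_equal(unname(subject_nc_metrics(b[-1, , drop = FALSE], b)["theta.HbO"]),
               0.3)
  expect_error(subject_nc_metrics(b[0, , drop = FALSE], b),
               class = "nvc_data_error")
})

test_that("unimodal power metrics follow their closed forms", {
  env_c <- structure(list(envelope = matrix(2, 4, 100), fs = 250,
                          band = c(3.5, 8.2)), class = "band_envelope")
  set.seed(12)
  hb <- structure(list(hbo = matrix(rnorm(6 * 5000), 6),
                       hbr = matrix(0, 6, 5000), fs = 10.42,
                       geometry = channel_geometry(4, 2)),
                  class = "hemoglobin")
  p <- unimodal_powers(list(theta = env_c), hb)
  expect_equal(unname(p["power.theta"]), 4)
  expect_equal(unname(p["power.HbO"]), 1, tolerance = 0.05)
  expect_equal(unname(p["power.HbR"]), 0)
})

test_that("short-channel regression removes planted scalp contamination", {
  # zero neural coupling, strong scalp leakage: with the short-channel
  # nuisances the NC metrics shrink towards zero versus omitting them
  reps <- 20
  with_short <- numeric(reps); without_short <- numeric(reps)
  for (r in seq_len(reps)) {
    spec <- coupling_spec(scalp_gain_long = 0.6, noise_sd_od = 0.005)
    sub <- simulate_subject(spec, 73, 0, 90, seed = 900 + r, n_channels = 8)
    f <- nc_fit(sub)
    with_short[r] <- mean(abs(f$metrics))
    # refit without nuisance columns: regress the same responses on the
    # band columns only
    rec <- filter_eeg(sub$eeg)
    globals <- lapply(band_power_envelopes(rec), global_envelope_pca)
    hb <- od_to_hemoglobin(filter_od(wavelet_motion_correct(
      intensity_to_od(sub$intensity))), 73)
    bc <- hrf_band_columns(globals, 1)
    long <- which(hb$geometry$role == "long")
    ys <- lapply(long, function(ch)
      nvcoupling:::block_resample(hb$hbo[ch, ], hb$fs, 1))
    n <- min(c(lengths(bc), lengths(ys)))
    rows <- 31:n
    Xb <- cbind(vapply(bc, function(v) as.numeric(scale(v[rows])),
                       numeric(length(rows))), 1)
    betas <- vapply(ys, function(y)
      stats::lm.fit(Xb, as.numeric(scale(y[rows])))$coefficients[1:3],
      numeric(3))
    without_short[r] <- mean(abs(rowMeans(betas)))
  }
  expect_lt(mean(with_short), mean(without_short))
  expect_gt(mean(without_short - with_short), 0)
})

test_that("estimated couplings regress on the truth with positive slope", {
  truths <- rep(c(0, 0.2, 0.4, 0.6), each = 5)
  est <- vapply(seq_along(truths), function(i) {
    spec <- coupling_spec(beta = matrix(c(truths[i], 0, 0, 0, 0, 0), 3, 2))
    sub <- simulate_subject(spec, 73, 0, 120, seed = 1200 + i, n_channels = 8)
    nc_fit(sub)$metrics["theta.HbO"]
  }, numeric(1))
  fit <- lm(est ~ truths)
  expect_gt(coef(fit)[2], 0)
  expect_gt(summary(fit)$r.squared, 0.5)
})
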