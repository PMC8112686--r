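vol_std <- detection_volume(0.25, 5)

test_that("the ACF estimator matches the direct-lag oracle and its invariances", {
  set.seed(7)
  x <- 50 + 10 * cos(2 * pi * (1:8192) / 64) + rnorm(8192, 0, 2)
  a <- compute_acf(x, subrecord_len = 4096, sample_rate_hz = 1e5)
  oracle <- (direct_acf_oracle(x[1:4096], 2048) +
               direct_acf_oracle(x[4097:8192], 2048)) / 2
  expect_lt(max(abs(a$g - oracle)), 1e-10)
  expect_true(all(diff(a$tau_s) > 0))

  # scale invariance: G is normalized by the squared mean
  a2 <- compute_acf(3.7 * x, subrecord_len = 4096, sample_rate_hz = 1e5)
  expect_equal(a2$g, a$g, tolerance = 1e-12)

  # constant trace: zero correlation at every positive lag
  ac <- compute_acf(rep(5, 8192), subrecord_len = 2048, sample_rate_hz = 1e5)
  expect_equal(max(abs(ac$g)), 0)

  expect_error(compute_acf(x[1:100], subrecord_len = 4096, sample_rate_hz = 1e5),
               "shorter")
  expect_error(compute_acf(rep(0, 8192), subrecord_len = 2048,
                           sample_rate_hz = 1e5), "dark")
})

test_that("noiseless model curves are refit exactly (1 and 2 components)", {
  a1 <- gen_acf_curve(11.5, g0 = 0.1, volume = vol_std)
  f1 <- fit_acf(a1, 1, vol_std, weights = FALSE)
  expect_lt(abs(f1$components$d_um2_s - 11.5) / 11.5, 0.005)
  # G(0) of the fitted model equals the summed amplitudes
  expect_equal(acf_diffusion_model(0, f1$components$g0, f1$components$tau_d_s, 5),
               sum(f1$components$g0))

  a2 <- gen_acf_curve(c(15.8, 0.34), g0 = c(0.05, 0.05), volume = vol_std,
                      lags_s = 10^seq(-6, 1, length.out = 80))
  f2 <- fit_acf(a2, 2, vol_std, weights = FALSE)
  expect_equal(f2$components$tau_d_s, sort(f2$components$tau_d_s))
  expect_lt(abs(f2$components$d_um2_s[1] - 15.8) / 15.8, 0.02)
  expect_lt(abs(f2$components$d_um2_s[2] - 0.34) / 0.34, 0.02)

  expect_error(fit_acf(a1[1:10, ], 1, vol_std), ">= 20 lags")
})

test_that("volume calibration inverts the diffusion-time relation", {
  # tau_D = 36.76 us at D = 425 um^2/s gives w_r = 0.25 um
  cal <- gen_acf_curve(425, g0 = 0.1, volume = vol_std,
                       lags_s = 10^seq(-7, -1, length.out = 60))
  v <- calibrate_volume(cal, d_known_um2_s = 425, omega_prior = 5)
  expect_equal(v$w_r_um, 0.25, tolerance = 1e-3)
  expect_equal(v$w_r_um, sqrt(4 * 425 * 36.76e-6), tolerance = 2e-3)

  # round trip: the calibrated volume returns the standard's D exactly
  fstd <- fit_acf(cal, 1, v)
  expect_equal(fstd$components$d_um2_s[1], 425, tolerance = 0.5)

  # scaling: doubling tau_D scales w_r by sqrt(2)
  cal2 <- gen_acf_curve(425 / 2, g0 = 0.1, volume = vol_std,
                        lags_s = 10^seq(-7, -1, length.out = 60))
  v2 <- calibrate_volume(cal2, d_known_um2_s = 425, omega_prior = 5)
  expect_equal(v2$w_r_um / v$w_r_um, sqrt(2), tolerance = 1e-3)
})

test_that("diffusion_from_tau implements D = w_r^2 / (4 tau)", {
  expect_equal(diffusion_from_tau(1.359e-3, vol_std), 11.50, tolerance = 1e-3)
  expect_equal(diffusion_from_tau(2 * 1.359e-3, vol_std),
               diffusion_from_tau(1.359e-3, vol_std) / 2)
  v4 <- detection_volume(0.5, 5)
  expect_equal(diffusion_from_tau(1.359e-3, v4),
               4 * diffusion_from_tau(1.359e-3, vol_std))
  expect_error(diffusion_from_tau(-1, vol_std), "> 0")
  expect_error(detection_volume(0.25, 0.8), "> 1")
})

test_that("model choice prefers one component when two collapse or are noisy", {
  # degenerate: both components converge to the same diffusion time
  a1 <- gen_acf_curve(11.5, g0 = 0.1, volume = vol_std, noise_sd = 5e-5, seed = 2)
  f1 <- fit_acf(a1, 1, vol_std, weights = FALSE)
  f2 <- fit_acf(a1, 2, vol_std, weights = FALSE)
  ch <- choose_model(f1, f2)
  expect_equal(ch$model, 1L)

  # clean two-species data with a 30-fold D ratio keeps two components
  a2 <- gen_acf_curve(c(15.8, 0.5), g0 = c(0.05, 0.05), volume = vol_std,
                      lags_s = 10^seq(-6, 1, length.out = 80),
                      noise_sd = 2e-4, seed = 3)
  ch2 <- choose_model(fit_acf(a2, 1, vol_std, weights = FALSE),
                      fit_acf(a2, 2, vol_std, weights = FALSE))
  expect_equal(ch2$model, 2L)

  # one-species data across seeds: model 1 chosen in >= 90% of runs
  picks <- vapply(1:50, function(s) {
    a <- gen_acf_curve(11.5, g0 = 0.1, volume = vol_std, noise_sd = 2e-3, seed = s)
    fa <- fit_acf(a, 1, vol_std, weights = FALSE)
    fb <- tryCatch(fit_acf(a, 2, vol_std, weights = FALSE),
                   error = function(e) NULL)
    if (is.null(fb)) 1L else choose_model(fa, fb)$model
  }, integer(1))
  expect_gte(mean(picks == 1L), 0.9)
})

test_that("Brownian-dynamics traces recover the generating diffusion", {
  tr <- gen_fcs_trace(11.5, rate_hz = 2e5, n_molecules = 10, duration_s = 60,
                      sample_rate_hz = 5e4, seed = 3)
  ac <- compute_acf(tr, subrecord_len = 65536)
  ft <- fit_acf(log_resample_acf(ac), 1, vol_std)
  td_true <- 0.25^2 / (4 * 11.5)
  expect_lt(abs(ft$components$tau_d_s - td_true) / td_true, 0.10)
  expect_lt(abs(ft$components$d_um2_s - 11.5) / 11.5, 0.12)
})
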