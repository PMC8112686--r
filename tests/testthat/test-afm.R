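alpha <- 20 * pi / 180

test_that("contact point is located exactly on clean curves and flagged when absent", {
  fc <- gen_force_curve(13e3, alpha_rad = alpha, contact_nm = 500)
  cp <- find_contact_point(fc)
  expect_false(cp$flagged)
  expect_lt(abs(cp$z_nm - 500), diff(fc$z_nm)[1])  # within one sample

  # pure baseline: no contact anywhere
  flat <- gen_force_curve(13e3, alpha_rad = alpha, contact_nm = 2000,
                          max_indentation_nm = 1e-3, noise_sd_nn = 0.01, seed = 2)
  expect_true(find_contact_point(flat)$flagged)
})

test_that("contact detection is robust to force noise", {
  fmax <- max(gen_force_curve(13e3, alpha_rad = alpha)$force_nn)
  errs <- vapply(1:100, function(s) {
    fc <- gen_force_curve(13e3, alpha_rad = alpha, contact_nm = 500, n = 300,
                          noise_sd_nn = 0.05 * fmax, seed = s)
    cp <- find_contact_point(fc)
    abs(cp$z_nm - 500) / diff(fc$z_nm)[1]
  }, numeric(1))
  expect_lt(median(errs), 5)
})

test_that("the cone-model fit recovers the generating modulus exactly", {
  for (e_true in c(3.4e3, 13e3, 18e3, 37e3, 46e3)) {
    fc <- gen_force_curve(e_true, alpha_rad = alpha, contact_nm = 432)
    fit <- fit_sneddon(fc, find_contact_point(fc))
    expect_lt(abs(fit$e_pa - e_true) / e_true, 1e-3)
  }
})

test_that("fitted modulus obeys force scaling and Poisson-ratio algebra", {
  fc <- gen_force_curve(13e3, alpha_rad = alpha)
  cp <- find_contact_point(fc)
  fit <- fit_sneddon(fc, cp)
  fc2 <- fc
  fc2$force_nn <- 2 * fc2$force_nn
  fit2 <- fit_sneddon(fc2, cp)
  expect_equal(fit2$e_pa, 2 * fit$e_pa, tolerance = 1e-9)

  # same data refit at nu = 0.3 scales E by (1-0.3^2)/(1-0.5^2)
  fit3 <- fit_sneddon(fc, cp, nu = 0.3)
  expect_equal(fit3$e_pa / fit$e_pa, (1 - 0.09) / (1 - 0.25), tolerance = 1e-9)

  # abscissa shift moves the contact, leaves E unchanged
  fcs <- fc
  fcs$z_nm <- fcs$z_nm + 250
  cps <- find_contact_point(fcs)
  expect_equal(cps$z_nm, cp$z_nm + 250, tolerance = 1e-6)
  expect_equal(fit_sneddon(fcs, cps)$e_pa, fit$e_pa, tolerance = 1e-9)
})

test_that("per-experiment aggregation gives the documented summary statistics", {
  fits <- tibble::tibble(experiment = c("a", "b", "c"), e_pa = c(12e3, 13e3, 14e3))
  ms <- aggregate_modulus(fits)
  expect_equal(ms$e_mean_pa, 13e3)
  expect_equal(ms$e_se_pa, sd(c(12, 13, 14)) / sqrt(3) * 1e3)
  expect_equal(ms$n_curves, 3)

  single <- aggregate_modulus(tibble::tibble(experiment = "a", e_pa = 10e3))
  expect_equal(single$e_mean_pa, 10e3)
  expect_true(is.na(single$e_se_pa))
  expect_error(aggregate_modulus(tibble::tibble(experiment = character(),
                                                e_pa = numeric())), "no fits")
})

test_that("simulated multi-experiment campaigns recover the true modulus", {
  fmax <- max(gen_force_curve(13e3, alpha_rad = alpha)$force_nn)
  fits <- purrr::map_dfr(1:4, function(exp_i) {
    e <- vapply(1:25, function(ci) {
      fc <- gen_force_curve(13e3, alpha_rad = alpha, n = 300,
                            noise_sd_nn = 0.05 * fmax,
                            seed = exp_i * 1000 + ci)
      fit_sneddon(fc, find_contact_point(fc))$e_pa
    }, numeric(1))
    tibble::tibble(experiment = as.character(exp_i), e_pa = e)
  })
  ms <- aggregate_modulus(fits)
  expect_lt(abs(ms$e_mean_pa - 13e3), 2 * 13e3 * 0.02)
  expect_lt(abs(ms$e_mean_pa - 13e3) / 13e3, 0.02)
})

test_that("force curves round-trip through the CSV reader", {
  fc <- gen_force_curve(13e3, alpha_rad = alpha)
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(z_nm = fc$z_nm, force_nn = fc$force_nn), path)
  rd <- read_force_curve(path, alpha_rad = alpha)
  expect_equal(rd$force_nn, fc$force_nn)
  fit <- fit_sneddon(rd, find_contact_point(rd))
  expect_lt(abs(fit$e_pa - 13e3) / 13e3, 1e-3)

  # deflection input with a spring constant
  path2 <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(z_nm = fc$z_nm,
                                  deflection_nm = fc$force_nn / 0.06), path2)
  rd2 <- read_force_curve(path2, alpha_rad = alpha, spring_constant_n_m = 0.06)
  expect_equal(rd2$force_nn, fc$force_nn, tolerance = 1e-12)
})
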