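# Fluorescence correlation spectroscopy: normalized intensity
# autocorrelation by sub-record averaging, 1-/2-component 3D-diffusion fits,
# detection-volume calibration and the characteristic-time <-> diffusion
# conversion.

new_acf_curve <- function(tau_s, g, g_se, n_subrecords) {
  tb <- tibble::tibble(tau_s = tau_s, g = g, g_se = g_se)
  structure(tb, class = c("acf_curve", class(tb)), n_subrecords = n_subrecords)
}

#' Normalized intensity autocorrelation of an FCS trace
#'
#' The trace is cut into non-overlapping sub-records; each is mean-subtracted,
#' zero-padded to twice its length (to avoid circular aliasing), correlated
#' via FFT with unbiased per-lag normalization, and divided by its squared
#' mean, giving `G(tau) = <dI(t) dI(t+tau)> / <I>^2` per sub-record. Curves
#' are averaged across sub-records and the per-lag standard error reported.
#' Lags are truncated to half the sub-record length.
#'
#' @param trace An `intensity_trace` from [gen_fcs_trace()], or any numeric
#'   vector with a `sample_rate_hz` argument.
#' @param subrecord_len Sub-record length in samples (default 2^13 = 8192).
#' @param sample_rate_hz Sampling rate; taken from the trace attribute when
#'   present.
#' @param zero_pad Zero-pad sub-records to twice their length before the FFT.
#' @return An `acf_curve` tibble: `tau_s`, `g`, `g_se`; attribute
#'   `n_subrecords` (dark sub-records with zero mean are excluded and
#'   counted in attribute `n_excluded`).
#' @export
compute_acf <- function(trace, subrecord_len = 8192, sample_rate_hz = NULL,
                        zero_pad = TRUE) {
  x <- if (is.data.frame(trace)) trace$counts else as.numeric(trace)
  rate <- sample_rate_hz %||% attr(trace, "sample_rate_hz")
  check_that(!is.null(rate), "sampling rate unknown; pass `sample_rate_hz`")
  n <- length(x)
  check_that(n >= 2 * subrecord_len,
             "trace (%d samples) shorter than two sub-records (%d)", n, subrecord_len)
  n_sub <- n %/% subrecord_len
  L <- subrecord_len
  nlag <- L %/% 2
  gsum <- matrix(NA_real_, n_sub, nlag)
  excluded <- 0L
  for (s in seq_len(n_sub)) {
    seg <- x[((s - 1) * L + 1):(s * L)]
    mu <- mean(seg)
    if (mu <= 0) { excluded <- excluded + 1L; next }
    d <- seg - mu
    m <- if (zero_pad) 2 * L else L
    fd <- fft(c(d, numeric(m - L)))
    ac <- Re(fft(fd * Conj(fd), inverse = TRUE))[1:(nlag + 1)] / m
    # unbiased: with zero-padding, lag k sums L-k products
    denom <- if (zero_pad) (L - 0:nlag) else rep(L, nlag + 1)
    gsum[s, ] <- (ac[-1] / denom[-1]) / mu^2
  }
  check_that(excluded < n_sub, "all sub-records dark (zero mean)")
  keep <- stats::complete.cases(gsum)
  gmat <- gsum[keep, , drop = FALSE]
  g <- colMeans(gmat)
  g_se <- if (nrow(gmat) > 1) apply(gmat, 2, sd) / sqrt(nrow(gmat)) else rep(NA_real_, nlag)
  out <- new_acf_curve(tau_s = (1:nlag) / rate, g = g, g_se = g_se,
                       n_subrecords = sum(keep))
  attr(out, "n_excluded") <- excluded
  out
}

#' Resample an ACF onto a quasi-logarithmic lag grid
#'
#' Multi-tau-style rebinning: lags are averaged within log-spaced bins so
#' every decade contributes comparable weight to the fit.
#'
#' @param acf An `acf_curve`.
#' @param points_per_decade Bins per decade of lag.
#' @return An `acf_curve` on the coarse grid (SEs combined in quadrature).
#' @export
log_resample_acf <- function(acf, points_per_decade = 12) {
  lt <- log10(acf$tau_s)
  br <- seq(min(lt) - 1e-9, max(lt) + 1e-9,
            length.out = max(2, ceiling(diff(range(lt)) * points_per_decade)))
  bin <- cut(lt, br, labels = FALSE)
  agg <- dplyr::tibble(bin = bin, tau = acf$tau_s, g = acf$g, se = acf$g_se) |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(tau_s = mean(.data$tau), g = mean(.data$g),
                     g_se = sqrt(sum(.data$se^2)) / dplyr::n(), n = dplyr::n(),
                     .groups = "drop")
  new_acf_curve(agg$tau_s, agg$g, agg$g_se, attr(acf, "n_subrecords"))
}

#' Fit the 1- or 2-component diffusion model to an ACF
#'
#' Weighted (1/SE^2 when per-lag SEs are available) nonlinear least squares
#' of [acf_diffusion_model()]. Components are reported sorted fast to slow
#' (`tau_d1 < tau_d2`); diffusion coefficients require `volume`.
#'
#' @param acf An `acf_curve`.
#' @param n_components 1 or 2.
#' @param volume A [detection_volume()]; its `omega` is held fixed, and
#'   `w_r_um` converts characteristic times to diffusion coefficients.
#' @param weights Use per-lag SE weighting when available.
#' @return An `fcs_fit`: list with `components` (tibble `g0`, `g0_se`,
#'   `tau_d_s`, `tau_d_se`, `d_um2_s`, `d_se`), `model`, `residual_rms`,
#'   `selection_note`, `fit` (the nls object).
#' @export
fit_acf <- function(acf, n_components = 1, volume = detection_volume(),
                    weights = TRUE) {
  check_that(n_components %in% 1:2, "`n_components` must be 1 or 2")
  check_that(nrow(acf) >= 20, "need >= 20 lags to fit")
  check_that(log10(max(acf$tau_s) / min(acf$tau_s)) >= 2,
             "lags must span >= 2 decades")
  omega <- volume$omega
  dat <- data.frame(tau = acf$tau_s, g = acf$g)
  w <- if (weights && all(is.finite(acf$g_se)) && all(acf$g_se > 0))
    1 / acf$g_se^2 else rep(1, nrow(dat))
  g0_init <- max(acf$g[1], 1e-4)
  # lag where G first falls to half its small-lag value
  half <- acf$tau_s[which(acf$g <= g0_init / 2)[1]]
  if (is.na(half)) half <- stats::median(acf$tau_s)
  fit <- if (n_components == 1) {
    minpack.lm::nlsLM(
      g ~ acf_diffusion_model(tau, g0, td, omega),
      data = dat, weights = w,
      start = list(g0 = g0_init, td = half),
      lower = c(1e-8, 1e-9), upper = c(10, 100),
      control = minpack.lm::nls.lm.control(maxiter = 200))
  } else {
    # the Levenberg-Marquardt core directly: a degenerate (single-species)
    # curve collapses the two components onto each other, which makes the
    # converged Jacobian singular and the nls wrapper refuse the result
    resid_fn <- function(p) sqrt(w) * (acf_diffusion_model(dat$tau, p[1:2], p[3:4], omega) - dat$g)
    out <- NULL
    for (sep in c(10, 3)) {
      cand <- minpack.lm::nls.lm(
        par = c(g0_init / 2, g0_init / 2, half / sep, half * sep),
        lower = c(1e-8, 1e-8, 1e-9, 1e-9), upper = c(10, 10, 100, 100),
        fn = resid_fn, control = minpack.lm::nls.lm.control(maxiter = 400))
      if (is.null(out) || cand$deviance < out$deviance) out <- cand
    }
    check_that(out$info %in% 1:4, "2-component fit did not converge: %s", out$message)
    out
  }
  if (n_components == 1) {
    cf <- coef(fit)
    se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, length(cf)))
    resid_unw <- stats::residuals(fit)
  } else {
    cf <- setNames(fit$par, c("g1", "g2", "td1", "td2"))
    dof <- nrow(dat) - 4L
    s2 <- fit$deviance / max(dof, 1)
    covm <- tryCatch(solve(fit$hessian) * s2, error = function(e) NULL)
    se <- if (is.null(covm)) setNames(rep(NA_real_, 4), names(cf))
          else setNames(sqrt(pmax(diag(covm), 0)), names(cf))
    resid_unw <- acf_diffusion_model(dat$tau, cf[1:2], cf[3:4], omega) - dat$g
  }
  if (n_components == 1) {
    comp <- tibble::tibble(g0 = cf[["g0"]], g0_se = se[["g0"]],
                           tau_d_s = cf[["td"]], tau_d_se = se[["td"]])
  } else {
    comp <- tibble::tibble(g0 = c(cf[["g1"]], cf[["g2"]]),
                           g0_se = c(se[["g1"]], se[["g2"]]),
                           tau_d_s = c(cf[["td1"]], cf[["td2"]]),
                           tau_d_se = c(se[["td1"]], se[["td2"]]))
    comp <- comp[order(comp$tau_d_s), ]
  }
  comp$d_um2_s <- volume$w_r_um^2 / (4 * comp$tau_d_s)
  comp$d_se <- comp$d_um2_s * comp$tau_d_se / comp$tau_d_s
  note <- ""
  if (n_components == 2) {
    joint <- sqrt(sum(comp$tau_d_se^2))
    rel_gap <- abs(diff(comp$tau_d_s)) / max(comp$tau_d_s)
    if ((is.finite(joint) && abs(diff(comp$tau_d_s)) <= joint) ||
        any(!is.finite(comp$tau_d_se)) || rel_gap < 1e-3)
      note <- "component collapse: tau_d1 = tau_d2 within joint SE"
  }
  structure(list(components = comp, model = n_components,
                 residual_rms = sqrt(mean(resid_unw^2)),
                 selection_note = note, fit = fit, volume = volume),
            class = "fcs_fit")
}

#' @export
print.fcs_fit <- function(x, ...) {
  cat(sprintf("<fcs_fit> %d-component model\n", x$model))
  print(x$components, digits = 4)
  if (nzchar(x$selection_note)) cat("note:", x$selection_note, "\n")
  invisible(x)
}

#' @export
tidy.fcs_fit <- function(x, ...) {
  comp <- x$components
  tibble::tibble(
    term = paste0(rep(c("g0_", "tau_d_", "d_"), each = nrow(comp)),
                  rep(seq_len(nrow(comp)), 3)),
    estimate = c(comp$g0, comp$tau_d_s, comp$d_um2_s),
    std.error = c(comp$g0_se, comp$tau_d_se, comp$d_se))
}

#' @export
glance.fcs_fit <- function(x, ...) {
  tibble::tibble(model = x$model, residual_rms = x$residual_rms,
                 d1_um2_s = x$components$d_um2_s[1],
                 d2_um2_s = if (nrow(x$components) > 1) x$components$d_um2_s[2] else NA_real_)
}

#' Calibrate the detection volume from a standard of known diffusion
#'
#' Fits the 1-component model to the ACF of a calibration dye (e.g.
#' fluorescein, D = 425 um^2/s in aqueous solution) and inverts
#' `tau_D = w_r^2 / (4 D)` for the radial waist.
#'
#' @param acf An `acf_curve` measured on the standard.
#' @param d_known_um2_s Known diffusion coefficient of the standard.
#' @param omega_prior Aspect ratio held fixed during the fit.
#' @return A [detection_volume()] with calibrated `w_r_um`.
#' @export
calibrate_volume <- function(acf, d_known_um2_s = 425, omega_prior = 5) {
  fit <- fit_acf(acf, 1, detection_volume(w_r_um = 0.25, omega = omega_prior))
  tau_d <- fit$components$tau_d_s[1]
  detection_volume(w_r_um = sqrt(4 * d_known_um2_s * tau_d), omega = omega_prior)
}

#' Diffusion coefficient from a characteristic correlation time
#'
#' `D = w_r^2 / (4 tau_D)`.
#'
#' @param tau_d_s Characteristic time, s (> 0).
#' @param volume A [detection_volume()].
#' @return Diffusion coefficient, um^2/s.
#' @export
diffusion_from_tau <- function(tau_d_s, volume) {
  check_that(all(tau_d_s > 0), "`tau_d_s` must be > 0")
  volume$w_r_um^2 / (4 * tau_d_s)
}

#' Choose between the 1- and 2-component diffusion models
#'
#' Prefers the 1-component description when the 2-component fit is
#' degenerate (its characteristic times collapse within their joint SE) or
#' unreliable (any parameter relative SE above `max_rel_se`) while the
#' 1-component fit is not substantially worse (residual F-ratio below
#' `f_ratio`); otherwise the 2-component model is kept.
#'
#' @param fit1,fit2 [fit_acf()] results on the same curve with 1 and 2
#'   components.
#' @param max_rel_se Maximum tolerated relative SE of any 2-component
#'   parameter.
#' @param f_ratio Maximum tolerated (rms1 / rms2)^2 for the simpler model.
#' @return A list: `model` (1 or 2), `chosen` (the fit), `rationale`.
#' @export
choose_model <- function(fit1, fit2, max_rel_se = 0.5, f_ratio = 2) {
  check_that(fit1$model == 1 && fit2$model == 2,
             "`fit1`/`fit2` must be the 1- and 2-component fits")
  collapse <- nzchar(fit2$selection_note)
  rel_se <- with(fit2$components,
                 c(g0_se / g0, tau_d_se / tau_d_s))
  noisy_pars <- any(!is.finite(rel_se)) || any(rel_se > max_rel_se)
  fr <- (fit1$residual_rms / fit2$residual_rms)^2
  if (collapse) {
    rationale <- "2-component characteristic times collapse; one diffusive component describes the data"
    model <- 1L
  } else if (noisy_pars && fr <= f_ratio) {
    rationale <- sprintf(
      "2-component parameter errors exceed %.0f%% and the 1-component residual is not worse than F-ratio %.2g",
      100 * max_rel_se, f_ratio)
    model <- 1L
  } else {
    rationale <- "2-component parameters are well determined and improve the residual"
    model <- 2L
  }
  list(model = model, chosen = if (model == 1) fit1 else fit2,
       rationale = rationale)
}
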