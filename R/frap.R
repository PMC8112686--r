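# FRAP normalization and reaction-dominant recovery fitting. In the
# reaction-dominant limit (unbound diffusion much faster than binding
# kinetics) the recovery of a photobleached adhesion region follows
# F(t) = m (1 - exp(-k_off t)), so the fitted rate is the dissociation rate
# constant of the protein from the adhesion complex.

#' Read a FRAP region-intensity trace from CSV
#'
#' Expects columns `t_s`, `i_ph_fa`, `i_c_fa`, `i_cyt` and optionally
#' `i_bkg`; pre-bleach frames have `t_s < 0` and the bleach is at `t = 0`.
#'
#' @param path CSV file path.
#' @return A `frap_trace` tibble (see [gen_frap_trace()]).
#' @export
read_frap_trace <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  need <- c("t_s", "i_ph_fa", "i_c_fa", "i_cyt")
  check_that(all(need %in% names(tb)), "FRAP CSV needs columns %s",
             paste(need, collapse = ", "))
  structure(tibble::as_tibble(tb), class = c("frap_trace", class(tibble::tibble())),
            n_pre = sum(tb$t_s < 0))
}

#' Double-normalize a FRAP trace into a recovery curve
#'
#' First normalization divides the bleached-adhesion intensity (above the
#' cytoplasmic level) by the control-adhesion intensity (above the same
#' level), cancelling shared acquisition photobleaching:
#' `I_FRAP(t) = (I_PH-FA - I_Cyt) / (I_C-FA - I_Cyt)`. Second normalization
#' anchors the curve between the immediate post-bleach value `I_o` and the
#' pre-bleach mean `I_PRE`: `F(t) = (I_FRAP - I_o) / (I_PRE - I_o)`.
#'
#' @param trace A `frap_trace` (from [gen_frap_trace()] or
#'   [read_frap_trace()]).
#' @param subtract_background Subtract `i_bkg` from all regions before the
#'   first normalization (off by default; the background enters no other
#'   step).
#' @return A `recovery_curve` tibble with post-bleach rows only: `t_s`
#'   (0 at the first post-bleach frame), `f`; attributes `i_pre`, `i_o`.
#' @export
normalize_frap <- function(trace, subtract_background = FALSE) {
  n_pre <- attr(trace, "n_pre") %||% sum(trace$t_s < 0)
  check_that(n_pre >= 1, "need at least one pre-bleach frame")
  check_that(sum(trace$t_s >= 0) >= 5, "need at least 5 post-bleach frames")
  check_that(all(diff(trace$t_s) > 0), "timestamps must be strictly increasing")
  ph <- trace$i_ph_fa; ctrl <- trace$i_c_fa; cyt <- trace$i_cyt
  if (subtract_background) {
    check_that(!is.null(trace$i_bkg), "no `i_bkg` column to subtract")
    inform("background subtraction enabled")
    ph <- ph - trace$i_bkg; ctrl <- ctrl - trace$i_bkg; cyt <- cyt - trace$i_bkg
  }
  denom <- ctrl - cyt
  if (any(denom <= 0)) {
    abort(sprintf("control intensity crosses the cytoplasm level at frame %d",
                  which(denom <= 0)[1]))
  }
  i_frap <- (ph - cyt) / denom
  pre <- trace$t_s < 0
  i_pre <- mean(i_frap[pre])
  post <- which(!pre)
  i_o <- i_frap[post[1]]
  check_that(i_pre > i_o, "no bleach achieved: pre-bleach level does not exceed post-bleach")
  f <- (i_frap[post] - i_o) / (i_pre - i_o)
  tb <- tibble::tibble(t_s = trace$t_s[post] - trace$t_s[post[1]], f = f)
  structure(tb, class = c("recovery_curve", class(tb)),
            i_pre = i_pre, i_o = i_o)
}

#' Fit the reaction-dominant recovery model
#'
#' Nonlinear least squares of `F(t) = m (1 - exp(-k_off t))`. Initial values:
#' `m0` is the mean of the last three points and `k0 = ln 2 / t_half` with
#' `t_half` the time F first reaches `m0 / 2`. Bounds
#' `k_off in (1e-4, 10) 1/s`, `m in (0, 1.5)`; a solution touching a bound
#' or a fitted span shorter than `1/k_off` is flagged.
#'
#' @param curve A `recovery_curve` from [normalize_frap()].
#' @param weights Optional per-point weights (unweighted by default).
#' @return A `kinetics_fit`: list with `k_off`, `k_off_se`, `m`, `m_se`,
#'   `t_res_s`, `t_res_se` (first-order propagation), `residual_rms`,
#'   `flags` (character vector).
#' @export
#' @examples
#' tr <- gen_frap_trace(k_off = 0.034, m = 0.57)
#' fit_recovery(normalize_frap(tr))$k_off
fit_recovery <- function(curve, weights = NULL) {
  check_that(nrow(curve) >= 10, "need >= 10 post-bleach points")
  m0 <- mean(tail(curve$f, 3))
  check_that(is.finite(m0), "recovery curve contains non-finite values")
  if (m0 <= 0.02) abort("no recovery detected (plateau at zero); cannot fit")
  t_half <- curve$t_s[which(curve$f >= m0 / 2)[1]]
  if (is.na(t_half) || t_half <= 0) t_half <- stats::median(curve$t_s)
  k0 <- log(2) / t_half
  w <- weights %||% rep(1, nrow(curve))
  fit <- minpack.lm::nlsLM(
    f ~ m * (1 - exp(-k * t_s)), data = curve, weights = w,
    start = list(m = min(max(m0, 0.05), 1.4), k = min(max(k0, 2e-4), 9)),
    lower = c(0, 1e-4), upper = c(1.5, 10),
    control = minpack.lm::nls.lm.control(maxiter = 200))
  cf <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) c(NA_real_, NA_real_))
  flags <- character()
  if (cf[["k"]] <= 1.001e-4 || cf[["k"]] >= 9.99 || cf[["m"]] >= 1.499)
    flags <- c(flags, "bound")
  if (cf[["m"]] > 1) flags <- c(flags, "mobile_fraction_above_1")
  if (max(curve$t_s) < 1 / cf[["k"]]) flags <- c(flags, "span_below_1_over_koff")
  structure(list(k_off = cf[["k"]], k_off_se = se[[2]],
                 m = cf[["m"]], m_se = se[[1]],
                 t_res_s = 1 / cf[["k"]],
                 t_res_se = se[[2]] / cf[["k"]]^2,
                 residual_rms = sqrt(mean(stats::residuals(fit)^2)),
                 flags = flags, fit = fit),
            class = "kinetics_fit")
}

#' @export
print.kinetics_fit <- function(x, ...) {
  cat(sprintf("<kinetics_fit> k_off = %.4g +/- %.2g 1/s, m = %.3g +/- %.2g, t_res = %.3g s\n",
              x$k_off, x$k_off_se, x$m, x$m_se, x$t_res_s))
  if (length(x$flags)) cat("flags:", paste(x$flags, collapse = ", "), "\n")
  invisible(x)
}

#' @export
tidy.kinetics_fit <- function(x, ...) {
  tibble::tibble(term = c("k_off", "m", "t_res"),
                 estimate = c(x$k_off, x$m, x$t_res_s),
                 std.error = c(x$k_off_se, x$m_se, x$t_res_se))
}

#' @export
glance.kinetics_fit <- function(x, ...) {
  tibble::tibble(k_off = x$k_off, k_off_se = x$k_off_se, m = x$m, m_se = x$m_se,
                 t_res_s = x$t_res_s, t_res_se = x$t_res_se,
                 residual_rms = x$residual_rms, flagged = length(x$flags) > 0)
}

#' Residence time from a kinetics fit
#'
#' The mean time a molecule remains bound, `t_res = 1 / k_off`, with its SE
#' by first-order propagation (`SE_t = SE_k / k_off^2`). Always derived from
#' the unrounded fitted rate.
#'
#' @param fit A `kinetics_fit`, or a bare `k_off` value.
#' @param k_off_se Optional SE when `fit` is a bare value.
#' @return A tibble: `t_res_s`, `t_res_se`.
#' @export
residence_time <- function(fit, k_off_se = NA_real_) {
  if (inherits(fit, "kinetics_fit")) {
    k <- fit$k_off; kse <- fit$k_off_se
  } else {
    k <- fit; kse <- k_off_se
  }
  check_that(all(k > 0), "`k_off` must be > 0")
  tibble::tibble(t_res_s = 1 / k, t_res_se = kse / k^2)
}
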