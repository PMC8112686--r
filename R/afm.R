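# Substrate elasticity from AFM force-distance curves: contact-point
# detection by exhaustive piecewise fitting, Sneddon cone-model fit, and
# per-experiment aggregation.

#' Read a two-column AFM force curve
#'
#' Accepts `z_nm,force_nn` directly, or `z_nm,deflection_nm` together with a
#' cantilever spring constant and (optional) deflection sensitivity, in which
#' case force is computed as `k * sensitivity * deflection`.
#'
#' @param path CSV/TSV file with header `z_nm,force_nn` or `z_nm,deflection_nm`.
#' @param alpha_rad Tip half-opening angle, rad (required metadata; the
#'   instrument does not embed it).
#' @param nu Sample Poisson's ratio.
#' @param spring_constant_n_m Cantilever spring constant, N/m (needed for
#'   deflection input).
#' @param sensitivity Deflection sensitivity correction factor (default 1).
#' @return A `force_curve` tibble as produced by [gen_force_curve()].
#' @export
read_force_curve <- function(path, alpha_rad, nu = 0.5,
                             spring_constant_n_m = NULL, sensitivity = 1) {
  tb <- readr::read_delim(path, show_col_types = FALSE, trim_ws = TRUE)
  check_that("z_nm" %in% names(tb), "input must have a `z_nm` column")
  if (!"force_nn" %in% names(tb)) {
    check_that("deflection_nm" %in% names(tb) && !is.null(spring_constant_n_m),
               "need `force_nn`, or `deflection_nm` plus `spring_constant_n_m`")
    tb$force_nn <- spring_constant_n_m * sensitivity * tb$deflection_nm
  }
  tb <- tb[order(tb$z_nm), c("z_nm", "force_nn")]
  structure(tibble::as_tibble(tb), class = c("force_curve", class(tibble::tibble())),
            alpha_rad = alpha_rad, nu = nu)
}

#' Locate the tip-sample contact point of a force curve
#'
#' Exhaustive piecewise-model search: every interior sample is tried as the
#' contact point; before it the force is modelled as a constant baseline,
#' after it as baseline plus a quadratic in the indentation (the Sneddon
#' form). The candidate minimizing the total sum of squared residuals wins;
#' ties break to the earliest candidate.
#'
#' @param curve A `force_curve` tibble (`z_nm`, `force_nn`).
#' @param min_baseline Minimum number of baseline samples required before the
#'   contact candidate.
#' @param min_post Minimum number of post-contact samples required.
#' @return A list of class `contact_point`: `index`, `z_nm`, `sse`,
#'   `flagged` (TRUE when no acceptable candidate exists, e.g. contact at the
#'   first sample or no contact at all).
#' @export
find_contact_point <- function(curve, min_baseline = 10, min_post = 10) {
  z <- curve$z_nm; f <- curve$force_nn
  n <- length(z)
  check_that(n >= 50, "force curve must have >= 50 samples")
  check_that(all(diff(z) > 0), "`z_nm` must be strictly increasing")
  cand <- seq(min_baseline, n - min_post)
  sse <- rep(Inf, length(cand))
  # cumulative sums let the baseline SSE be O(1) per candidate
  cf <- cumsum(f); cf2 <- cumsum(f^2)
  for (j in seq_along(cand)) {
    i <- cand[j]
    sse_base <- cf2[i] - cf[i]^2 / i
    d2 <- (z[(i + 1):n] - z[i])^2
    fp <- f[(i + 1):n]
    # least-squares F = b + s * d2 with s >= 0
    X <- cbind(1, d2)
    beta <- tryCatch(solve(crossprod(X), crossprod(X, fp)), error = function(e) NULL)
    if (is.null(beta)) next
    if (beta[2] < 0) { beta <- c(mean(fp), 0) }
    res <- fp - X %*% beta
    sse[j] <- sse_base + sum(res^2)
  }
  best <- which.min(sse)  # which.min takes the first (earliest) minimum
  idx <- cand[best]
  # continuous refinement of z0 between the neighbouring samples: same
  # piecewise model (flat baseline, quadratic beyond z0), SSE minimized in z0
  piece_sse <- function(z0) {
    pre <- z <= z0
    if (sum(pre) < 2 || sum(!pre) < 3) return(Inf)
    s1 <- sum((f[pre] - mean(f[pre]))^2)
    d2 <- (z[!pre] - z0)^2
    X <- cbind(1, d2)
    beta <- solve(crossprod(X), crossprod(X, f[!pre]))
    if (beta[2] < 0) beta <- c(mean(f[!pre]), 0)
    s1 + sum((f[!pre] - X %*% beta)^2)
  }
  z0 <- z[idx]
  if (idx > 1 && idx < n) {
    opt <- stats::optimize(piece_sse, c(z[idx - 1], z[idx + 1]))
    if (is.finite(opt$objective) && opt$objective <= sse[best]) z0 <- opt$minimum
  }
  # no real contact: the quadratic adds nothing over a single flat baseline
  flat_sse <- cf2[n] - cf[n]^2 / n
  spread <- sd(f[seq_len(max(min_baseline, idx))])
  post_rise <- mean(tail(f, min_post)) - mean(head(f, min_baseline))
  flagged <- !is.finite(sse[best]) || post_rise < 5 * max(spread, 1e-12) ||
    idx <= min_baseline
  structure(list(index = idx, z_nm = z0, sse = sse[best], flagged = flagged),
            class = "contact_point")
}

#' Fit the Sneddon cone-contact model to a force curve
#'
#' Linearizes `F = 2/pi * E/(1-nu^2) * tan(alpha) * delta^2` as a straight
#' line in `delta^2` over an indentation window and converts the slope to the
#' Young's modulus `E = slope * pi (1 - nu^2) / (2 tan alpha)`.
#'
#' @param curve A `force_curve` tibble.
#' @param contact Contact position in nm, or a [find_contact_point()] result.
#' @param nu Poisson's ratio (default from the curve's attribute, else 0.5).
#' @param alpha_rad Tip half-angle (default from the curve's attribute).
#' @param window Fit window as fractions of the maximum indentation,
#'   `c(lower, upper)`.
#' @return A list of class `elasticity_fit`: `e_pa`, `e_se_pa`,
#'   `contact_nm`, `fit_range_nm`, `residual_rms_nn`, `n_points`.
#' @export
#' @examples
#' fc <- gen_force_curve(13e3, alpha_rad = 20 * pi / 180)
#' cp <- find_contact_point(fc)
#' fit_sneddon(fc, cp)$e_pa
fit_sneddon <- function(curve, contact, nu = NULL, alpha_rad = NULL,
                        window = c(0.1, 0.9)) {
  nu <- nu %||% attr(curve, "nu") %||% 0.5
  alpha_rad <- alpha_rad %||% attr(curve, "alpha_rad")
  check_that(!is.null(alpha_rad), "tip half-angle `alpha_rad` is required")
  contact_nm <- if (inherits(contact, "contact_point")) contact$z_nm else contact
  delta <- curve$z_nm - contact_nm
  post <- delta > 0
  dmax <- max(delta[post])
  lo <- window[1] * dmax; hi <- min(window[2], 1) * dmax
  if (window[2] > 1) warn("fit window extends beyond the data; truncated")
  sel <- post & delta >= lo & delta <= hi
  check_that(sum(sel) >= 20, "need >= 20 post-contact samples in the fit window")
  d2 <- delta[sel]^2
  fit <- lm(curve$force_nn[sel] ~ d2)
  slope <- coef(fit)[["d2"]]
  check_that(slope > 0, "non-positive force-indentation slope; curve rejected")
  slope_se <- sqrt(vcov(fit)["d2", "d2"])
  conv <- 1e9 * pi * (1 - nu^2) / (2 * tan(alpha_rad))
  structure(list(e_pa = slope * conv, e_se_pa = slope_se * conv,
                 contact_nm = contact_nm, fit_range_nm = c(lo, hi),
                 residual_rms_nn = sqrt(mean(fit$residuals^2)),
                 n_points = sum(sel), nu = nu, alpha_rad = alpha_rad),
            class = "elasticity_fit")
}

#' @export
print.elasticity_fit <- function(x, ...) {
  cat(sprintf("<elasticity_fit> E = %.3g +/- %.2g kPa (contact %.0f nm, %d pts)\n",
              x$e_pa / 1e3, x$e_se_pa / 1e3, x$contact_nm, x$n_points))
  invisible(x)
}

#' @export
tidy.elasticity_fit <- function(x, ...) {
  tibble::tibble(term = c("e_pa", "contact_nm"),
                 estimate = c(x$e_pa, x$contact_nm),
                 std.error = c(x$e_se_pa, NA_real_))
}

#' @export
glance.elasticity_fit <- function(x, ...) {
  tibble::tibble(e_pa = x$e_pa, e_se_pa = x$e_se_pa, contact_nm = x$contact_nm,
                 residual_rms_nn = x$residual_rms_nn, n_points = x$n_points)
}

#' Aggregate elasticity fits into a per-substrate modulus summary
#'
#' Each experiment contributes its mean modulus; the grand mean is the mean
#' of the per-experiment means and its error the standard error across
#' experiments (sd / sqrt(n_experiments)).
#'
#' @param fits A tibble with columns `experiment` and `e_pa` (one row per
#'   accepted curve fit), e.g. built from [fit_sneddon()] results.
#' @param bins Number of histogram bins for the modulus distribution.
#' @return A list of class `modulus_summary`: `e_mean_pa`, `e_se_pa` (NA for
#'   a single experiment), `n_curves`, `n_experiments`, `per_experiment`
#'   (tibble), `histogram` (tibble `mid_pa`, `count`).
#' @export
aggregate_modulus <- function(fits, bins = 20) {
  check_that(nrow(fits) >= 1, "no fits to aggregate")
  check_that(all(c("experiment", "e_pa") %in% names(fits)),
             "`fits` needs `experiment` and `e_pa` columns")
  per <- fits |>
    dplyr::group_by(.data$experiment) |>
    dplyr::summarise(e_mean_pa = mean(.data$e_pa), n = dplyr::n(), .groups = "drop")
  h <- graphics::hist(fits$e_pa, breaks = bins, plot = FALSE)
  structure(list(
    e_mean_pa = mean(per$e_mean_pa),
    e_se_pa = if (nrow(per) > 1) sd(per$e_mean_pa) / sqrt(nrow(per)) else NA_real_,
    n_curves = nrow(fits), n_experiments = nrow(per),
    per_experiment = per,
    histogram = tibble::tibble(mid_pa = h$mids, count = h$counts)),
    class = "modulus_summary")
}

#' @export
print.modulus_summary <- function(x, ...) {
  cat(sprintf("<modulus_summary> E = %.3g +/- %.2g kPa (%d curves, %d experiments)\n",
              x$e_mean_pa / 1e3, x$e_se_pa / 1e3, x$n_curves, x$n_experiments))
  invisible(x)
}

#' @export
glance.modulus_summary <- function(x, ...) {
  tibble::tibble(e_mean_pa = x$e_mean_pa, e_se_pa = x$e_se_pa,
                 n_curves = x$n_curves, n_experiments = x$n_experiments)
}
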