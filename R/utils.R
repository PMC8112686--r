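# Shared numerical helpers. All spatial quantities are in micrometres unless a
# suffix says otherwise; stresses are Pa, forces nN, times seconds.

#' Discrete Fourier frequencies in angular units
#'
#' Wavevector components for an `n`-point grid of spacing `d`, in rad per unit
#' of `d`, laid out in standard FFT order (DC first, negative frequencies in
#' the second half).
#'
#' @param n Number of grid points.
#' @param d Grid spacing.
#' @return Numeric vector of length `n`.
#' @keywords internal
fft_freq <- function(n, d = 1) {
  i <- c(seq(0L, floor((n - 1) / 2)), seq(-floor(n / 2), -1L))
  2 * pi * i / (n * d)
}

# Stop unless a condition holds; message is sprintf-style.
check_that <- function(cond, msg, ...) {
  if (!isTRUE(cond)) abort(sprintf(msg, ...))
  invisible(TRUE)
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

# Bilinear interpolation of matrix `m` (rows = y, cols = x) at fractional
# 1-based coordinates. Points outside the grid are clamped to the border.
bilinear <- function(m, x, y) {
  nr <- nrow(m); nc <- ncol(m)
  x <- pmin(pmax(x, 1), nc)
  y <- pmin(pmax(y, 1), nr)
  x0 <- pmin(floor(x), nc - 1L); y0 <- pmin(floor(y), nr - 1L)
  fx <- x - x0; fy <- y - y0
  m[cbind(y0, x0)] * (1 - fx) * (1 - fy) +
    m[cbind(y0, x0 + 1)] * fx * (1 - fy) +
    m[cbind(y0 + 1, x0)] * (1 - fx) * fy +
    m[cbind(y0 + 1, x0 + 1)] * fx * fy
}

# Quadratic (Sneddon) force law: E in Pa, indentation in nm, force in nN.
sneddon_force_nn <- function(delta_nm, e_pa, nu, alpha_rad) {
  (2 / pi) * (e_pa / (1 - nu^2)) * tan(alpha_rad) * delta_nm^2 * 1e-9
}

# Prefactor s such that F[nN] = s * delta[nm]^2 for given E (Pa).
sneddon_slope <- function(e_pa, nu, alpha_rad) {
  (2 / pi) * (e_pa / (1 - nu^2)) * tan(alpha_rad) * 1e-9
}

# Young's modulus (Pa) from a fitted F = s * delta^2 slope (nN/nm^2).
sneddon_modulus_from_slope <- function(slope, nu, alpha_rad) {
  slope * 1e9 * pi * (1 - nu^2) / (2 * tan(alpha_rad))
}
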