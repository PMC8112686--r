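# Synthetic traction scenes: elliptical focal-adhesion patches of uniform
# stress placed at the periphery of a model cell on a linear-elastic,
# isotropic, incompressible half-space. The scene is the ground truth against
# which displacement extraction and traction reconstruction are checked.

#' Elastic substrate parameters
#'
#' @param e_pa Young's modulus in Pa (must be positive).
#' @param nu Poisson's ratio, in `[0, 0.5]`; polyacrylamide hydrogels are
#'   treated as incompressible (`nu = 0.5`).
#' @param thickness_um Substrate thickness in micrometres (informational; the
#'   half-space model assumes thickness much larger than the deformations).
#' @return A list of class `elastic_substrate`.
#' @export
#' @examples
#' elastic_substrate(13e3)
elastic_substrate <- function(e_pa, nu = 0.5, thickness_um = 50) {
  check_that(is_scalar_number(e_pa) && e_pa > 0, "`e_pa` must be a positive number")
  check_that(is_scalar_number(nu) && nu >= 0 && nu <= 0.5,
             "`nu` must lie in [0, 0.5]")
  structure(list(e_pa = e_pa, nu = nu, thickness_um = thickness_um),
            class = "elastic_substrate")
}

#' Generate a ground-truth traction scene
#'
#' Builds a model cell (a closed polygon) with `n_patches` elliptical
#' focal-adhesion patches of uniform in-plane stress near its periphery,
#' pulling centripetally, on an elastic half-space. With
#' `enforce_balance = TRUE` (the default) patch stress vectors are corrected
#' so the total in-plane force integrates exactly to zero, as it must for an
#' isolated adherent cell.
#'
#' @param n_patches Number of adhesion patches (>= 1).
#' @param peak_stress_pa Patch stress magnitude in Pa; recycled, and jittered
#'   by `stress_jitter` (relative sd) per patch.
#' @param patch_area_um2 Mean patch area in square micrometres. Focal
#'   adhesions are of order 2.5 um^2.
#' @param cell_radius_um Mean radius of the cell boundary polygon.
#' @param extent_um Side of the square field of view, micrometres.
#' @param substrate An [elastic_substrate()].
#' @param pixel_size_um Pixel size used when the scene is rendered to images.
#' @param stress_jitter Relative sd of per-patch stress variation.
#' @param enforce_balance Correct patch vectors so the net force is zero.
#'   A single patch cannot be balanced; with `n_patches = 1` and
#'   `enforce_balance = TRUE` the correction would annihilate the patch, so
#'   it is refused.
#' @param seed Integer seed; the scene is a pure function of its arguments.
#' @return An object of class `traction_scene`: a list with `patches` (a
#'   tibble: `x`, `y`, `a`, `b`, `theta`, `stress_pa`, `dx`, `dy`),
#'   `boundary`, `substrate`, `extent_um`, `pixel_size_um`, `seed`.
#' @export
#' @examples
#' sc <- make_traction_scene(n_patches = 8, seed = 1)
#' sum(with(sc$patches, stress_pa * pi * a * b * dx))  # net x-force ~ 0
make_traction_scene <- function(n_patches = 10,
                                peak_stress_pa = 500,
                                patch_area_um2 = 2.5,
                                cell_radius_um = 12,
                                extent_um = 36,
                                substrate = elastic_substrate(13e3),
                                pixel_size_um = 0.069,
                                stress_jitter = 0.2,
                                enforce_balance = TRUE,
                                seed = 1L) {
  check_that(n_patches >= 1, "at least one patch is required")
  check_that(all(peak_stress_pa >= 0), "peak stresses must be non-negative")
  check_that(cell_radius_um + sqrt(patch_area_um2 / pi) < extent_um / 2,
             "cell (radius %.1f um) does not fit in the %.1f um extent",
             cell_radius_um, extent_um)
  check_that(!(enforce_balance && n_patches == 1),
             "a single patch cannot be force-balanced; use n_patches >= 2 or enforce_balance = FALSE")

  set.seed(seed)
  cx <- extent_um / 2
  cy <- extent_um / 2

  # slightly lobed cell boundary
  phi <- seq(0, 2 * pi, length.out = 121)
  lobe <- 1 + 0.12 * sin(3 * phi + runif(1, 0, 2 * pi))
  boundary <- tibble::tibble(x = cx + cell_radius_um * lobe * cos(phi),
                             y = cy + cell_radius_um * lobe * sin(phi))

  ang <- runif(n_patches, 0, 2 * pi)
  rad <- runif(n_patches, 0.6, 0.85) * cell_radius_um
  asp <- runif(n_patches, 1, 2)
  area <- patch_area_um2 * exp(rnorm(n_patches, 0, 0.05))
  b <- sqrt(area / (pi * asp))
  a <- asp * b
  stress <- rep_len(peak_stress_pa, n_patches) *
    pmax(exp(rnorm(n_patches, 0, stress_jitter)), 0.05)
  # centripetal pull with a little angular jitter; patches elongated along pull
  pull <- ang + pi + rnorm(n_patches, 0, 0.15)
  patches <- tibble::tibble(
    x = cx + rad * cos(ang), y = cy + rad * sin(ang),
    a = a, b = b, theta = ang + pi,
    stress_pa = stress, dx = cos(pull), dy = sin(pull))

  if (enforce_balance) {
    aeff <- pi * patches$a * patches$b
    net <- c(sum(patches$stress_pa * aeff * patches$dx),
             sum(patches$stress_pa * aeff * patches$dy))
    corr <- net / sum(aeff)
    vx <- patches$stress_pa * patches$dx - corr[1]
    vy <- patches$stress_pa * patches$dy - corr[2]
    mag <- sqrt(vx^2 + vy^2)
    patches$stress_pa <- mag
    patches$dx <- vx / mag
    patches$dy <- vy / mag
  }

  structure(list(patches = patches, boundary = boundary,
                 substrate = substrate, extent_um = extent_um,
                 pixel_size_um = pixel_size_um, seed = seed),
            class = "traction_scene")
}

#' @export
print.traction_scene <- function(x, ...) {
  cat(sprintf("<traction_scene> %d patches, extent %.1f um, E = %.3g kPa, seed %d\n",
              nrow(x$patches), x$extent_um, x$substrate$e_pa / 1e3, x$seed))
  invisible(x)
}

#' Rasterize scene traction onto a regular grid
#'
#' Uniform stress inside each elliptical patch, zero outside. With
#' `balance = TRUE` the grid mean is subtracted so the zero-frequency Fourier
#' mode of the rendered traction is exactly zero, matching the force-balance
#' convention of the Fourier inversion (which drops that mode).
#'
#' @param scene A [make_traction_scene()] scene.
#' @param grid_n Number of grid points per side.
#' @param balance Subtract the grid-mean traction (see Details).
#' @return List with matrices `tx`, `ty` (Pa, row = y index increasing
#'   upward), grid-centre coordinate vectors `x`, `y` (um) and spacing `h`.
#' @export
scene_traction_grid <- function(scene, grid_n = 128, balance = TRUE) {
  h <- scene$extent_um / grid_n
  xs <- (seq_len(grid_n) - 0.5) * h
  tx <- matrix(0, grid_n, grid_n)
  ty <- matrix(0, grid_n, grid_n)
  for (i in seq_len(nrow(scene$patches))) {
    p <- scene$patches[i, ]
    rmax <- max(p$a, p$b)
    ix <- which(abs(xs - p$x) <= rmax + h)
    iy <- which(abs(xs - p$y) <= rmax + h)
    if (!length(ix) || !length(iy)) next
    dx <- outer(rep(1, length(iy)), xs[ix] - p$x)
    dy <- outer(xs[iy] - p$y, rep(1, length(ix)))
    xr <- dx * cos(p$theta) + dy * sin(p$theta)
    yr <- -dx * sin(p$theta) + dy * cos(p$theta)
    inside <- (xr / p$a)^2 + (yr / p$b)^2 <= 1
    tx[iy, ix] <- tx[iy, ix] + inside * p$stress_pa * p$dx
    ty[iy, ix] <- ty[iy, ix] + inside * p$stress_pa * p$dy
  }
  if (balance) {
    tx <- tx - mean(tx)
    ty <- ty - mean(ty)
  }
  list(tx = tx, ty = ty, x = xs, y = xs, h = h)
}

# Fourier-space Green's tensor of the elastic half-space (Boussinesq
# solution), evaluated on full wavevector grids. Returns the three distinct
# entries; the k = 0 entry is set to 0 (force-balance convention).
greens_tensor_grids <- function(kx, ky, substrate) {
  e <- substrate$e_pa; nu <- substrate$nu
  KX <- matrix(kx, nrow = length(ky), ncol = length(kx), byrow = TRUE)
  KY <- matrix(ky, nrow = length(ky), ncol = length(kx))
  k2 <- KX^2 + KY^2
  k <- sqrt(k2)
  pref <- 2 * (1 + nu) / (e * k^3)
  gxx <- pref * ((1 - nu) * k2 + nu * KY^2)
  gyy <- pref * ((1 - nu) * k2 + nu * KX^2)
  gxy <- -pref * nu * KX * KY
  gxx[1, 1] <- 0; gyy[1, 1] <- 0; gxy[1, 1] <- 0
  # The unpaired Nyquist modes of an even-length grid have no negative-k
  # partner; the odd-in-k off-diagonal term must vanish there to keep the
  # operator real-to-real (Hermitian output for Hermitian input).
  if (length(kx) %% 2 == 0) gxy[, length(kx) / 2 + 1] <- 0
  if (length(ky) %% 2 == 0) gxy[length(ky) / 2 + 1, ] <- 0
  list(gxx = gxx, gyy = gyy, gxy = gxy, k = k)
}

#' Half-space Green's operator at a single wavevector
#'
#' The 2x2 Fourier-space Boussinesq tensor mapping an in-plane traction mode
#' (Pa) to the surface displacement mode (um):
#' `G(k) = 2(1+nu)/(E k^3) * [[(1-nu)k^2 + nu ky^2, -nu kx ky],
#' [-nu kx ky, (1-nu)k^2 + nu kx^2]]`, symmetric positive definite for
#' `|k| > 0`.
#'
#' @param k Length-2 wavevector `(kx, ky)` in rad/um; must be nonzero.
#' @param substrate An [elastic_substrate()].
#' @return A 2x2 numeric matrix (um/Pa per mode).
#' @export
greens_operator <- function(k, substrate) {
  check_that(length(k) == 2 && sum(k^2) > 0, "`k` must be a nonzero 2-vector")
  e <- substrate$e_pa; nu <- substrate$nu
  k2 <- sum(k^2); kk <- sqrt(k2)
  pref <- 2 * (1 + nu) / (e * kk^3)
  pref * matrix(c((1 - nu) * k2 + nu * k[2]^2, -nu * k[1] * k[2],
                  -nu * k[1] * k[2], (1 - nu) * k2 + nu * k[1]^2), 2, 2)
}

#' Forward displacement field of a traction scene
#'
#' Computes the surface displacement generated by the scene's traction on the
#' half-space by Fourier-space multiplication with the Boussinesq Green's
#' tensor. By default the traction grid is zero-padded to twice its extent
#' before the FFT so that the implicit periodic images are pushed away from
#' the field of view.
#'
#' @param scene A [make_traction_scene()] scene.
#' @param grid_n Grid points per side for the displacement grid.
#' @param pad Zero-pad to 2x extent before the FFT.
#' @return A `displacement_field` tibble with columns `x`, `y`, `u`, `v` (um),
#'   `snr`, `outlier`; attributes `grid_x`, `grid_y`, `pixel_size_um`,
#'   `max_mag_um`.
#' @export
forward_displacement <- function(scene, grid_n = 128, pad = TRUE) {
  check_that(scene$substrate$e_pa > 0, "substrate must have E > 0")
  tr <- scene_traction_grid(scene, grid_n = grid_n)
  uv <- displacement_from_traction(tr$tx, tr$ty, tr$h, scene$substrate, pad = pad)
  new_displacement_field(tr$x, tr$y, uv$u, uv$v, pixel_size_um = tr$h)
}

# Core forward solve on raw matrices: u = IFFT(G(k) . FFT(T)), spacing h um.
displacement_from_traction <- function(tx, ty, h, substrate, pad = TRUE) {
  ny <- nrow(tx); nx <- ncol(tx)
  if (pad) {
    PX <- matrix(0, 2 * ny, 2 * nx); PY <- PX
    PX[seq_len(ny), seq_len(nx)] <- tx
    PY[seq_len(ny), seq_len(nx)] <- ty
    tx <- PX; ty <- PY
  }
  g <- greens_tensor_grids(fft_freq(ncol(tx), h), fft_freq(nrow(tx), h), substrate)
  fx <- fft(tx); fy <- fft(ty)
  ux <- g$gxx * fx + g$gxy * fy
  uy <- g$gxy * fx + g$gyy * fy
  u <- Re(fft(ux, inverse = TRUE)) / length(ux)
  v <- Re(fft(uy, inverse = TRUE)) / length(uy)
  if (pad) {
    u <- u[seq_len(ny), seq_len(nx)]
    v <- v[seq_len(ny), seq_len(nx)]
  }
  list(u = u, v = v)
}

# Construct the tidy displacement-field container from grid matrices.
new_displacement_field <- function(x, y, u, v, snr = NULL, outlier = NULL,
                                   pixel_size_um = NA_real_, window_size_px = NA_real_,
                                   overlap = NA_real_) {
  nx <- length(x); ny <- length(y)
  tb <- tibble::tibble(
    x = rep(x, each = ny), y = rep(y, times = nx),
    u = as.vector(u), v = as.vector(v),
    snr = if (is.null(snr)) Inf else as.vector(snr),
    outlier = if (is.null(outlier)) FALSE else as.vector(outlier))
  structure(tb, class = c("displacement_field", class(tb)),
            grid_x = x, grid_y = y, pixel_size_um = pixel_size_um,
            window_size_px = window_size_px, overlap = overlap,
            max_mag_um = max(sqrt(tb$u^2 + tb$v^2)))
}

# Extract one component of a gridded field tibble back into a matrix
# (rows = y, cols = x), relying on the construction order above.
field_matrix <- function(field, component) {
  gx <- attr(field, "grid_x"); gy <- attr(field, "grid_y")
  matrix(field[[component]], nrow = length(gy), ncol = length(gx))
}
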