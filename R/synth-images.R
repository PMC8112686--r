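# Rendering of fluorescent fiducial-bead image pairs. The PRE image is the
# deformed state (cell attached): beads are advected by +u from their
# reference positions. POST is the relaxed reference acquired after cell
# detachment. This sign convention matches acquisition order in a detachment
# experiment and is the one assumed by the displacement extraction.

#' Render a PRE/POST fiducial bead image pair
#'
#' Beads are placed uniformly at random over the field, imaged as 2D Gaussian
#' spots (a tractable stand-in for the microscope point-spread function), and
#' advected by the scene displacement for the PRE (deformed) image. Optional
#' shot noise (Poisson) and Gaussian read noise are applied.
#'
#' @param scene A [make_traction_scene()] scene (supplies extent and pixel size).
#' @param displacement A `displacement_field` from [forward_displacement()],
#'   or `NULL` for an undeformed pair.
#' @param bead_density_um2 Beads per square micrometre.
#' @param psf_sigma_px Gaussian spot sigma in pixels (must be >= 0.5).
#' @param peak_intensity Expected photon count at a spot centre.
#' @param noise `NULL` for noiseless images, or a list with `photon = TRUE`
#'   for Poisson shot noise and `read_sd` for additive Gaussian read noise sd.
#' @param drift_px Optional length-2 rigid shift (x, y, pixels) applied to the
#'   POST image, emulating stage drift between acquisitions.
#' @param seed Integer seed; images are bitwise reproducible.
#' @return A list of class `bead_image_pair`: matrices `pre`, `post`
#'   (row = y, col = x, non-negative), `pixel_size_um`, `bead_positions_um`
#'   (tibble of true reference positions), `seed`.
#' @export
render_bead_images <- function(scene, displacement = NULL,
                               bead_density_um2 = 0.3,
                               psf_sigma_px = 2,
                               peak_intensity = 200,
                               noise = NULL,
                               drift_px = c(0, 0),
                               seed = 1L) {
  check_that(psf_sigma_px >= 0.5, "`psf_sigma_px` must be >= 0.5 px")
  px <- scene$pixel_size_um
  n_px <- round(scene$extent_um / px)
  set.seed(seed)
  n_beads <- rpois(1, bead_density_um2 * scene$extent_um^2)
  bx <- runif(n_beads, 0, scene$extent_um)
  by <- runif(n_beads, 0, scene$extent_um)
  if (n_beads * (2 * pi * (psf_sigma_px * px)^2) > 2 * scene$extent_um^2)
    warn("bead density so high that spots merge over most of the field")

  if (is.null(displacement)) {
    ux <- numeric(n_beads); uy <- numeric(n_beads)
  } else {
    um <- field_matrix(displacement, "u")
    vm <- field_matrix(displacement, "v")
    h <- attr(displacement, "pixel_size_um")
    ux <- bilinear(um, bx / h + 0.5, by / h + 0.5)
    uy <- bilinear(vm, bx / h + 0.5, by / h + 0.5)
  }

  post <- render_spots(bx + drift_px[1] * px, by + drift_px[2] * px,
                       n_px, px, psf_sigma_px, peak_intensity)
  pre <- render_spots(bx + ux, by + uy, n_px, px, psf_sigma_px, peak_intensity)
  if (!is.null(noise)) {
    pre <- apply_camera_noise(pre, noise)
    post <- apply_camera_noise(post, noise)
  }
  structure(list(pre = pre, post = post, pixel_size_um = px,
                 bead_positions_um = tibble::tibble(x = bx, y = by),
                 seed = seed),
            class = "bead_image_pair")
}

# Additive Gaussian spots at positions (um) onto an n_px x n_px image.
render_spots <- function(bx, by, n_px, pixel_size_um, sigma_px, amp) {
  img <- matrix(0, n_px, n_px)
  cx <- bx / pixel_size_um + 0.5  # fractional pixel coordinate (1-based centers)
  cy <- by / pixel_size_um + 0.5
  w <- ceiling(4 * sigma_px)
  for (i in seq_along(bx)) {
    ix <- max(1L, floor(cx[i]) - w):min(n_px, floor(cx[i]) + w)
    iy <- max(1L, floor(cy[i]) - w):min(n_px, floor(cy[i]) + w)
    if (!length(ix) || !length(iy)) next
    gx <- exp(-(ix - cx[i])^2 / (2 * sigma_px^2))
    gy <- exp(-(iy - cy[i])^2 / (2 * sigma_px^2))
    img[iy, ix] <- img[iy, ix] + amp * outer(gy, gx)
  }
  img
}

apply_camera_noise <- function(img, noise) {
  if (isTRUE(noise$photon)) img[] <- rpois(length(img), pmax(img, 0))
  if (!is.null(noise$read_sd) && noise$read_sd > 0)
    img[] <- img + rnorm(length(img), 0, noise$read_sd)
  pmax(img, 0)
}

#' Write a bead image pair to TIFF files
#'
#' @param pair A [render_bead_images()] result.
#' @param pre_path,post_path Output file paths.
#' @return Invisibly, the two paths.
#' @export
write_bead_images <- function(pair, pre_path, post_path) {
  check_that(requireNamespace("tiff", quietly = TRUE),
             "the 'tiff' package is required to write TIFF files")
  sc <- max(pair$pre, pair$post, 1)
  tiff::writeTIFF(pair$pre / sc, pre_path, bits.per.sample = 16L)
  tiff::writeTIFF(pair$post / sc, post_path, bits.per.sample = 16L)
  invisible(c(pre_path, post_path))
}
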