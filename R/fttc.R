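# Traction reconstruction from a displacement field by regularized
# Fourier-transform traction cytometry: per-mode Tikhonov (zeroth-order)
# inversion of the half-space Green's tensor, L-curve selection of the
# regularization parameter, and cell-level / region-level summaries.

#' Reconstruct the traction field from a displacement field
#'
#' Per nonzero Fourier mode solves the regularized normal equations
#' `T(k) = (G'G + lambda^2 I)^-1 G' u(k)` with the Boussinesq Green's tensor
#' `G(k)`; the zero mode is set to zero, which enforces global force balance.
#' With `pad = TRUE` the displacement grid is zero-padded to twice its extent
#' before the FFT to suppress periodic wrap-around.
#'
#' @param field A complete `displacement_field` on a regular grid (run
#'   [interpolate_outliers()] first; NAs or remaining outliers are an error).
#' @param substrate An [elastic_substrate()].
#' @param lambda Tikhonov regularization parameter (same units as the
#'   singular values of `G`, um/Pa); `lambda = 0` is the unregularized
#'   inverse. Use [select_lambda()] for an objective choice.
#' @param pad Zero-pad to 2x extent before the FFT.
#' @return A `traction_field` tibble: `x`, `y` (um), `tx`, `ty`, `t_mag`
#'   (Pa); attributes `substrate`, `lambda`, `grid_x`, `grid_y`.
#' @export
fttc_inverse <- function(field, substrate, lambda = 0, pad = TRUE) {
  check_that(lambda >= 0, "`lambda` must be >= 0")
  check_that(!any(is.na(field$u)) && !any(is.na(field$v)),
             "displacement field contains NAs")
  check_that(!any(field$outlier), "field still has flagged outliers; interpolate first")
  gx <- attr(field, "grid_x"); gy <- attr(field, "grid_y")
  hx <- diff(gx); hy <- diff(gy)
  check_that(max(abs(hx - hx[1])) < 1e-9 * hx[1] && max(abs(hy - hy[1])) < 1e-9 * hy[1],
             "displacement grid must be regular")
  h <- hx[1]
  check_that(abs(hy[1] - h) < 1e-9 * h, "grid spacing must be equal in x and y")
  u <- field_matrix(field, "u"); v <- field_matrix(field, "v")
  ny <- nrow(u); nx <- ncol(u)
  if (pad) {
    U <- matrix(0, 2 * ny, 2 * nx); V <- U
    U[seq_len(ny), seq_len(nx)] <- u
    V[seq_len(ny), seq_len(nx)] <- v
    u <- U; v <- V
  }
  g <- greens_tensor_grids(fft_freq(ncol(u), h), fft_freq(nrow(u), h), substrate)
  fu <- fft(u); fv <- fft(v)
  # G is symmetric, so G'G = G^2; solve (G^2 + l^2 I) T = G u per mode.
  a <- g$gxx^2 + g$gxy^2 + lambda^2
  b <- g$gxy * (g$gxx + g$gyy)
  d <- g$gyy^2 + g$gxy^2 + lambda^2
  rx <- g$gxx * fu + g$gxy * fv
  ry <- g$gxy * fu + g$gyy * fv
  det <- a * d - b^2
  det[1, 1] <- 1  # zero mode handled below
  tx_hat <- (d * rx - b * ry) / det
  ty_hat <- (a * ry - b * rx) / det
  tx_hat[1, 1] <- 0; ty_hat[1, 1] <- 0
  tx <- Re(fft(tx_hat, inverse = TRUE)) / length(tx_hat)
  ty <- Re(fft(ty_hat, inverse = TRUE)) / length(ty_hat)
  if (pad) {
    tx <- tx[seq_len(ny), seq_len(nx)]
    ty <- ty[seq_len(ny), seq_len(nx)]
    # re-enforce force balance on the cropped window (the padded-grid zero
    # mode no longer guarantees a zero mean after cropping)
    tx <- tx - mean(tx)
    ty <- ty - mean(ty)
  }
  tb <- tibble::tibble(
    x = rep(gx, each = ny), y = rep(gy, times = nx),
    tx = as.vector(tx), ty = as.vector(ty),
    t_mag = as.vector(sqrt(tx^2 + ty^2)))
  structure(tb, class = c("traction_field", class(tb)),
            grid_x = gx, grid_y = gy, substrate = substrate, lambda = lambda,
            pixel_size_um = h)
}

#' Select the Tikhonov parameter by the L-curve maximum-curvature criterion
#'
#' Computes the residual norm `rho(lambda) = ||G T - u||` and solution norm
#' `eta(lambda) = ||T||` over a log-spaced lambda grid, smooths
#' `(log rho, log eta)` with a 5-point running mean, and returns the lambda
#' maximizing the curvature of the parametric curve. Ties break to the
#' smaller lambda (less smoothing).
#'
#' @param field A complete `displacement_field`.
#' @param substrate An [elastic_substrate()].
#' @param lambdas Lambda grid; default 28 log-spaced values spanning
#'   `10^-5` to `10^2` times the median Green's-tensor singular value of the
#'   grid (>= 4 decades are required).
#' @param pad Passed to [fttc_inverse()].
#' @return A list of class `lcurve_result`: `table` (tibble `lambda`, `rho`,
#'   `eta`, `curvature`), `lambda_opt`.
#' @export
select_lambda <- function(field, substrate, lambdas = NULL, pad = TRUE) {
  if (is.null(lambdas)) {
    gx <- attr(field, "grid_x")
    h <- gx[2] - gx[1]
    n <- length(gx)
    kmed <- pi / (2 * h)  # mid-band wavenumber
    s0 <- 2 * (1 + substrate$nu) / (substrate$e_pa * kmed)
    lambdas <- s0 * 10^seq(-5, 2, length.out = 28)
  }
  check_that(length(lambdas) >= 20 &&
               log10(max(lambdas) / min(lambdas)) >= 4,
             "lambda grid must have >= 20 points spanning >= 4 decades")
  lambdas <- sort(lambdas)
  u <- field_matrix(field, "u"); v <- field_matrix(field, "v")
  h <- attr(field, "grid_x")[2] - attr(field, "grid_x")[1]
  # Residual over the measured window only (the forward map of the cropped
  # reconstruction never reproduces the data exactly, so rho has a floor set
  # by discretization/truncation that rises with measurement noise -- this
  # floor is what gives the L-curve its corner).
  rho <- eta <- numeric(length(lambdas))
  for (i in seq_along(lambdas)) {
    tf <- fttc_inverse(field, substrate, lambda = lambdas[i], pad = pad)
    eta[i] <- sqrt(sum(tf$tx^2 + tf$ty^2))
    fwd <- displacement_from_traction(field_matrix(tf, "tx"), field_matrix(tf, "ty"),
                                      h, substrate, pad = pad)
    rho[i] <- sqrt(sum((fwd$u - u)^2 + (fwd$v - v)^2))
  }
  lr <- log(pmax(rho, .Machine$double.xmin))
  le <- log(pmax(eta, .Machine$double.xmin))
  sm <- function(x) stats::filter(x, rep(1 / 5, 5), sides = 2) |> as.numeric()
  lrs <- sm(lr); les <- sm(le)
  t <- log(lambdas)
  d1 <- function(x) c(NA, diff(x)) / c(NA, diff(t))
  r1 <- d1(lrs); e1 <- d1(les)
  r2 <- d1(r1); e2 <- d1(e1)
  # signed curvature of (log rho, log eta) parametrized by log lambda; the
  # orientation (rho increasing, eta decreasing) makes the corner the
  # maximum of this sign
  kappa <- (r2 * e1 - r1 * e2) / (r1^2 + e1^2)^1.5
  if (all(!is.finite(kappa) | is.na(kappa))) {
    warn("degenerate (flat) L-curve; returning the smallest lambda")
    opt <- 1L
  } else {
    opt <- which.max(replace(kappa, !is.finite(kappa), -Inf))  # first max: smaller lambda
  }
  structure(list(table = tibble::tibble(lambda = lambdas, rho = rho, eta = eta,
                                        curvature = as.numeric(kappa)),
                 lambda_opt = lambdas[opt]),
            class = "lcurve_result")
}

#' @export
print.lcurve_result <- function(x, ...) {
  cat(sprintf("<lcurve_result> %d lambdas in [%.3g, %.3g], lambda_opt = %.3g\n",
              nrow(x$table), min(x$table$lambda), max(x$table$lambda), x$lambda_opt))
  invisible(x)
}

#' Segment the cell footprint from an image
#'
#' Automatic path: global Otsu-style threshold (maximizing between-class
#' variance on a 256-bin histogram), morphological closing with a small
#' square structuring element, and retention of the largest connected
#' component. Manual path: a supplied polygon (um coordinates) is rasterized
#' verbatim.
#'
#' @param image Positive-valued image matrix (fluorescence or transmission),
#'   or `NULL` when a `polygon` is supplied.
#' @param pixel_size_um Pixel size, um.
#' @param polygon Optional tibble/data.frame with `x`, `y` (um): manual mask.
#' @param closing_px Structuring-element half-size for the closing step.
#' @return A list of class `cell_mask`: `mask` (logical matrix),
#'   `area_um2`, `pixel_size_um`, `polygon` (the input polygon or NULL).
#' @export
cell_mask <- function(image = NULL, pixel_size_um = 0.069, polygon = NULL,
                      closing_px = 2) {
  if (!is.null(polygon)) {
    check_that(!is.null(attr(image, "dim")) || is.matrix(image) || !is.null(image),
               "supply `image` (for its shape) together with `polygon`")
    nr <- nrow(image); nc <- ncol(image)
    xs <- (seq_len(nc) - 0.5) * pixel_size_um
    ys <- (seq_len(nr) - 0.5) * pixel_size_um
    inside <- point_in_polygon(rep(xs, each = nr), rep(ys, times = nc),
                               polygon$x, polygon$y)
    m <- matrix(inside, nr, nc)
  } else {
    check_that(is.matrix(image) && all(image >= 0), "image must be a non-negative matrix")
    check_that(sd(image) > 0, "constant image: nothing to segment")
    img01 <- (image - min(image)) / (max(image) - min(image))
    thr <- EBImage::otsu(EBImage::Image(img01), range = c(0, 1))
    m <- img01 > thr
    check_that(any(m), "empty mask after thresholding")
    if (closing_px > 0)
      m <- EBImage::closing(m, EBImage::makeBrush(2 * closing_px + 1, "box")) > 0
    lab <- EBImage::bwlabel(m)
    if (max(lab) > 1) {
      sizes <- tabulate(lab[lab > 0])
      m <- lab == which.max(sizes)
    }
  }
  check_that(any(m), "empty mask")
  structure(list(mask = m, area_um2 = sum(m) * pixel_size_um^2,
                 pixel_size_um = pixel_size_um, polygon = polygon),
            class = "cell_mask")
}


#' Cell-level deformation, traction and force summary
#'
#' Averages the displacement magnitude and traction magnitude over the grid
#' windows whose centres fall inside the cell mask, and reports the total
#' force as mean traction times mask area (`F = T_mean * A`, in nN:
#' Pa um^2 = 1e-3 nN). Histograms of |U|, Ux, Uy, |T|, Tx, Ty over the
#' in-mask windows are included.
#'
#' @param deformation A `displacement_field`.
#' @param traction A `traction_field` on the same grid.
#' @param mask A [cell_mask()] (or a polygon tibble with `x`, `y` in um).
#' @param bins Histogram bin count.
#' @return A list of class `cell_summary`: `area_um2`, `d_mean_um`,
#'   `t_mean_pa`, `f_total_nn`, `n_windows`, `histograms` (named list of
#'   tibbles `mid`, `count`).
#' @export
summarize_cell <- function(deformation, traction, mask, bins = 20) {
  if (inherits(mask, "cell_mask")) {
    poly <- mask$polygon
    if (is.null(poly)) {
      # in-mask test by nearest mask pixel at each window centre
      h <- mask$pixel_size_um
      ix <- pmin(pmax(round(deformation$x / h + 0.5), 1), ncol(mask$mask))
      iy <- pmin(pmax(round(deformation$y / h + 0.5), 1), nrow(mask$mask))
      inside <- mask$mask[cbind(iy, ix)]
    } else {
      inside <- point_in_polygon(deformation$x, deformation$y, poly$x, poly$y)
    }
    area <- mask$area_um2
  } else {
    inside <- point_in_polygon(deformation$x, deformation$y, mask$x, mask$y)
    area <- polygon_area(mask$x, mask$y)
  }
  check_that(any(inside), "mask does not overlap any grid window")
  dmag <- sqrt(deformation$u^2 + deformation$v^2)[inside]
  tmag <- traction$t_mag[inside]
  t_mean <- mean(tmag)
  hist_of <- function(x) {
    h <- graphics::hist(x, breaks = bins, plot = FALSE)
    tibble::tibble(mid = h$mids, count = h$counts)
  }
  structure(list(
    area_um2 = area, d_mean_um = mean(dmag), t_mean_pa = t_mean,
    f_total_nn = t_mean * area * 1e-3, n_windows = sum(inside),
    histograms = list(
      u_mag = hist_of(dmag), ux = hist_of(deformation$u[inside]),
      uy = hist_of(deformation$v[inside]), t_mag = hist_of(tmag),
      tx = hist_of(traction$tx[inside]), ty = hist_of(traction$ty[inside]))),
    class = "cell_summary")
}

#' @export
print.cell_summary <- function(x, ...) {
  cat(sprintf("<cell_summary> area %.0f um^2, D = %.3g um, T = %.3g Pa, F = %.3g nN\n",
              x$area_um2, x$d_mean_um, x$t_mean_pa, x$f_total_nn))
  invisible(x)
}

#' @export
glance.cell_summary <- function(x, ...) {
  tibble::tibble(area_um2 = x$area_um2, d_mean_um = x$d_mean_um,
                 t_mean_pa = x$t_mean_pa, f_total_nn = x$f_total_nn,
                 n_windows = x$n_windows)
}

# Shoelace polygon area.
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Mean traction around focal-adhesion regions
#'
#' Averages the traction magnitude over a square window of the given area
#' centred on each site (the region where a photobleaching experiment was
#' performed). Averaging over ~20 um^2 — several adhesions — reduces the
#' error of attributing traction to a single ~2.5 um^2 adhesion.
#'
#' @param traction A `traction_field`.
#' @param centers Tibble/data.frame with `x`, `y` (um) of region centres.
#' @param area_um2 Region area (square window), um^2.
#' @return A tibble: `region`, `x`, `y`, `t_region_pa`, `n_windows`,
#'   `clipped` (TRUE when more than half the window falls outside the field).
#' @export
region_average_traction <- function(traction, centers, area_um2 = 20) {
  gx <- attr(traction, "grid_x"); gy <- attr(traction, "grid_y")
  half <- sqrt(area_um2) / 2
  purrr::map_dfr(seq_len(nrow(centers)), function(i) {
    cx <- centers$x[i]; cy <- centers$y[i]
    check_that(cx >= min(gx) && cx <= max(gx) && cy >= min(gy) && cy <= max(gy),
               "region centre (%.1f, %.1f) outside the traction field", cx, cy)
    sel <- abs(traction$x - cx) <= half & abs(traction$y - cy) <= half
    full_n <- (2 * half / (gx[2] - gx[1]))^2
    tibble::tibble(region = i, x = cx, y = cy,
                   t_region_pa = mean(traction$t_mag[sel]),
                   n_windows = sum(sel),
                   clipped = sum(sel) < 0.5 * full_n)
  })
}
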