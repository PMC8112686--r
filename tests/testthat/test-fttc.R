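# Shared fixtures: one scene, its rasterized truth and forward field.
fttc_scene <- make_traction_scene(n_patches = 8, extent_um = 48,
                                  cell_radius_um = 12, seed = 11)
fttc_truth <- scene_traction_grid(fttc_scene, 64)
fttc_disp <- forward_displacement(fttc_scene, 64, pad = TRUE)

rel_l2 <- function(tf, truth) {
  tx <- cellmech:::field_matrix(tf, "tx")
  ty <- cellmech:::field_matrix(tf, "ty")
  sqrt(sum((tx - truth$tx)^2 + (ty - truth$ty)^2) / sum(truth$tx^2 + truth$ty^2))
}

test_that("the periodic inverse is exact and the padded inverse is close", {
  d0 <- forward_displacement(fttc_scene, 64, pad = FALSE)
  tf0 <- fttc_inverse(d0, fttc_scene$substrate, lambda = 0, pad = FALSE)
  expect_lt(rel_l2(tf0, fttc_truth), 1e-10)

  tf <- fttc_inverse(fttc_disp, fttc_scene$substrate, lambda = 0, pad = TRUE)
  expect_lt(rel_l2(tf, fttc_truth), 0.05)
})

test_that("reconstructed traction is force-balanced and zero for zero input", {
  tf <- fttc_inverse(fttc_disp, fttc_scene$substrate, lambda = 1e-5)
  expect_lt(sqrt(mean(tf$tx)^2 + mean(tf$ty)^2), 1e-6 * max(tf$t_mag))

  z <- fttc_disp
  z$u <- 0 * z$u; z$v <- 0 * z$v
  for (l in c(0, 1e-4)) {
    tfz <- fttc_inverse(z, fttc_scene$substrate, lambda = l)
    expect_equal(max(tfz$t_mag), 0)
  }
})

test_that("traction vanishes monotonically as the penalty grows", {
  norms <- vapply(c(1e-5, 1e-4, 1e-3, 1e-2, 1e-1),
                  function(l) sqrt(sum(fttc_inverse(fttc_disp, fttc_scene$substrate,
                                                    lambda = l)$t_mag^2)),
                  numeric(1))
  expect_true(all(diff(norms) < 0))
  expect_lt(norms[5] / norms[1], 1e-2)
})

test_that("inversion rejects broken inputs", {
  bad <- fttc_disp
  bad$u[3] <- NA
  expect_error(fttc_inverse(bad, fttc_scene$substrate), "NA")
  flagged <- fttc_disp
  flagged$outlier[2] <- TRUE
  expect_error(fttc_inverse(flagged, fttc_scene$substrate), "outlier")
  expect_error(fttc_inverse(fttc_disp, fttc_scene$substrate, lambda = -1), ">= 0")
})

test_that("the L-curve is monotone with a corner inside the grid", {
  lc <- select_lambda(fttc_disp, fttc_scene$substrate)
  expect_true(all(diff(lc$table$rho) >= -0.01 * max(lc$table$rho)))
  expect_true(all(diff(lc$table$eta) <= 0.01 * max(lc$table$eta)))
  expect_true(lc$lambda_opt %in% lc$table$lambda)
  expect_error(select_lambda(fttc_disp, fttc_scene$substrate,
                             lambdas = c(1e-5, 1e-4)), ">= 20 points")
})

test_that("L-curve regularization beats the unregularized inverse on noisy data", {
  umax <- max(sqrt(fttc_disp$u^2 + fttc_disp$v^2))
  wins <- vapply(1:5, function(s) {
    set.seed(300 + s)
    dn <- fttc_disp
    dn$u <- dn$u + rnorm(nrow(dn), 0, 0.05 * umax)
    dn$v <- dn$v + rnorm(nrow(dn), 0, 0.05 * umax)
    lo <- select_lambda(dn, fttc_scene$substrate)$lambda_opt
    err_reg <- rel_l2(fttc_inverse(dn, fttc_scene$substrate, lo), fttc_truth)
    err_unreg <- rel_l2(fttc_inverse(dn, fttc_scene$substrate, 0), fttc_truth)
    err_reg < err_unreg
  }, logical(1))
  expect_true(all(wins))
})

test_that("automatic segmentation recovers a bright disk", {
  n <- 200
  xs <- matrix(rep(1:n, each = n), n, n)
  ys <- t(xs)
  img <- 10 + 200 * ((xs - 100)^2 + (ys - 100)^2 < 60^2)
  set.seed(1)
  img <- img + matrix(rnorm(n^2, 0, 3), n, n)
  img <- pmax(img, 0)
  cm <- cell_mask(img, pixel_size_um = 0.1)
  expect_lt(abs(cm$area_um2 - pi * 36) / (pi * 36), 0.05)

  expect_error(cell_mask(matrix(5, 50, 50), 0.1), "constant")
})

test_that("polygon masks rasterize to the polygon area", {
  img <- matrix(1, 100, 100)
  poly <- tibble::tibble(x = c(2, 8, 8, 2), y = c(2, 2, 6, 6))
  cm <- cell_mask(img, pixel_size_um = 0.1, polygon = poly)
  true_area <- 6 * 4
  perimeter <- 20
  expect_lt(abs(cm$area_um2 - true_area), perimeter * 0.1)
})

test_that("cell summaries obey the F = T * A identity and window limits", {
  gx <- (1:10) - 0.5
  u <- matrix(0.2, 10, 10)
  d <- cellmech:::new_displacement_field(gx, gx, u, 0 * u, pixel_size_um = 1)
  tmag <- matrix(100, 10, 10)
  tb <- tibble::tibble(x = d$x, y = d$y, tx = 100, ty = 0, t_mag = 100)
  tf <- structure(tb, class = c("traction_field", class(tb)),
                  grid_x = gx, grid_y = gx,
                  substrate = elastic_substrate(13e3), lambda = 0,
                  pixel_size_um = 1)
  sq <- tibble::tibble(x = c(0, 10, 10, 0), y = c(0, 0, 10, 10))
  cs <- summarize_cell(d, tf, sq)
  expect_equal(cs$t_mean_pa, 100)
  expect_equal(cs$area_um2, 100)
  expect_equal(cs$f_total_nn, 100 * 100 * 1e-3)

  # a mask covering a single window returns that window's values
  one <- tibble::tibble(x = c(4, 5, 5, 4), y = c(4, 4, 5, 5))
  cs1 <- summarize_cell(d, tf, one)
  expect_equal(cs1$n_windows, 1)
  expect_equal(cs1$d_mean_um, 0.2)

  off <- tibble::tibble(x = c(50, 51, 51, 50), y = c(50, 50, 51, 51))
  expect_error(summarize_cell(d, tf, off), "overlap")
})

test_that("region averages sit between uniform and whole-field limits", {
  tf <- fttc_inverse(fttc_disp, fttc_scene$substrate, lambda = 0)
  ctr <- fttc_scene$patches[1, c("x", "y")]
  reg <- region_average_traction(tf, ctr, area_um2 = 20)
  # a 500 Pa patch inside the region pushes its mean above the whole-cell mean
  cs <- summarize_cell(fttc_disp, tf, fttc_scene$boundary)
  expect_gt(reg$t_region_pa, cs$t_mean_pa)

  # uniform field: region mean equals global mean; whole-field region too
  gx <- (1:10) - 0.5
  tbu <- tibble::tibble(x = rep(gx, each = 10), y = rep(gx, 10),
                        tx = 50, ty = 0, t_mag = 50)
  tfu <- structure(tbu, class = c("traction_field", class(tbu)),
                   grid_x = gx, grid_y = gx,
                   substrate = elastic_substrate(13e3), lambda = 0,
                   pixel_size_um = 1)
  regu <- region_average_traction(tfu, tibble::tibble(x = 5, y = 5), area_um2 = 9)
  expect_equal(regu$t_region_pa, 50)
  regall <- region_average_traction(tfu, tibble::tibble(x = 5, y = 5),
                                    area_um2 = 400)
  expect_equal(regall$t_region_pa, mean(tfu$t_mag))
  expect_true(regall$clipped)
  expect_error(region_average_traction(tfu, tibble::tibble(x = 50, y = 5)),
               "outside")
})

test_that("the inverse is equivariant under 90-degree scene rotation", {
  u <- cellmech:::field_matrix(fttc_disp, "u")
  v <- cellmech:::field_matrix(fttc_disp, "v")
  # rotate the field by 90 deg CCW: (x,y)->(-y,x), (u,v)->(-v,u)
  rot <- function(m) t(m)[rev(seq_len(ncol(m))), ]
  gx <- attr(fttc_disp, "grid_x")
  dr <- cellmech:::new_displacement_field(gx, gx, rot(-v), rot(u),
                                          pixel_size_um = attr(fttc_disp, "pixel_size_um"))
  tf <- fttc_inverse(fttc_disp, fttc_scene$substrate, lambda = 1e-5)
  tfr <- fttc_inverse(dr, fttc_scene$substrate, lambda = 1e-5)
  expect_equal(cellmech:::field_matrix(tfr, "tx"),
               rot(-cellmech:::field_matrix(tf, "ty")), tolerance = 1e-8)
  expect_equal(cellmech:::field_matrix(tfr, "ty"),
               rot(cellmech:::field_matrix(tf, "tx")), tolerance = 1e-8)
})
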