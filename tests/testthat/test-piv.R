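# Shared fixture: a bead field rendered once (no deformation).
piv_scene <- make_traction_scene(n_patches = 4, extent_um = 18,
                                 cell_radius_um = 6, seed = 5)
piv_pair <- render_bead_images(piv_scene, NULL, bead_density_um2 = 1.2, seed = 9)
px_um <- piv_pair$pixel_size_um

test_that("drift alignment recovers integer, zero and subpixel shifts", {
  # exact drift rendered into the POST bead positions (no resampling)
  drifted <- render_bead_images(piv_scene, NULL, bead_density_um2 = 1.2,
                                drift_px = c(3, -2), seed = 9)
  al <- align_drift(drifted$pre, drifted$post, c(20, 20, 100, 100))
  expect_equal(unname(al$shift_px), c(3, -2), tolerance = 0.02)

  al0 <- align_drift(piv_pair$post, piv_pair$post, c(20, 20, 100, 100))
  expect_equal(unname(al0$shift_px), c(0, 0), tolerance = 1e-6)

  sub <- render_bead_images(piv_scene, NULL, bead_density_um2 = 1.2,
                            drift_px = c(0.4, 0), seed = 9)
  al_sub <- align_drift(sub$pre, sub$post, c(20, 20, 128, 128))
  expect_lt(abs(al_sub$shift_px[1] - 0.4), 0.1)
  expect_lt(abs(al_sub$shift_px[2]), 0.1)

  expect_error(align_drift(piv_pair$pre, piv_pair$post, c(1, 1, 32, 32)), "64x64")
  flat_a <- matrix(1, 200, 200)
  expect_error(align_drift(flat_a, flat_a, c(10, 10, 100, 100)), "flat")
})

test_that("the plane pair with maximum displacement is selected", {
  post <- piv_pair$post[1:128, 1:128]
  still <- post
  moved <- cellmech:::shift_image(post, 4, 0)
  sel <- select_plane_pair(list(still, moved, still), list(post),
                          window_px = 64, pixel_size_um = px_um)
  expect_equal(sel$pre_index, 2)
  expect_equal(sel$post_index, 1)

  # all-identical planes: tie breaks to the first pair
  sel0 <- select_plane_pair(list(still, still), list(still, still),
                           window_px = 64, pixel_size_um = px_um)
  expect_equal(c(sel0$pre_index, sel0$post_index), c(1, 1))
  expect_error(select_plane_pair(list(), list(still)), "at least one")
})

test_that("multi-pass PIV recovers uniform translations to subpixel accuracy", {
  post <- piv_pair$post
  pre <- cellmech:::shift_image(post, 5, 0)
  f <- multipass_piv(pre, post, piv_config(c(64, 32, 16)), pixel_size_um = px_um)
  ok <- f$snr > 1.3
  expect_gt(mean(ok), 0.5)
  expect_lt(max(abs(f$u[ok] / px_um - 5)), 0.1)
  expect_lt(max(abs(f$v[ok] / px_um)), 0.1)

  # subpixel translation rendered exactly into the bead positions: the POST
  # image is drifted by -2.4 px, so the PRE pattern sits at +2.4 px
  sub <- render_bead_images(piv_scene, NULL, bead_density_um2 = 1.2,
                            drift_px = c(-2.4, 0), seed = 9)
  fs <- multipass_piv(sub$pre, sub$post, piv_config(c(64, 32, 16)),
                      pixel_size_um = px_um)
  fs <- filter_field(fs, piv_config(c(64, 32, 16)))
  oks <- !fs$outlier
  expect_lt(sqrt(mean((fs$u[oks] / px_um - 2.4)^2)), 0.1)
  expect_lt(sqrt(mean((fs$v[oks] / px_um)^2)), 0.1)

  # identical images give a zero field
  f0 <- multipass_piv(post, post, piv_config(c(64, 32, 16)), pixel_size_um = px_um)
  expect_lt(max(abs(c(f0$u, f0$v))), 1e-9)

  expect_error(multipass_piv(post[1:32, 1:32], post[1:32, 1:32],
                             piv_config(c(64, 32))), "larger")
})

test_that("PIV is equivariant under common and relative translations", {
  post <- piv_pair$post
  pre <- cellmech:::shift_image(post, 3, 0)
  f1 <- multipass_piv(pre, post, piv_config(c(64, 32)), pixel_size_um = px_um)
  # translate BOTH images: field unchanged (interior windows)
  pre2 <- cellmech:::shift_image(pre, 2, 1)
  post2 <- cellmech:::shift_image(post, 2, 1)
  f2 <- multipass_piv(pre2, post2, piv_config(c(64, 32)), pixel_size_um = px_um)
  ok <- f1$snr > 1.3 & f2$snr > 1.3
  expect_lt(max(abs(f2$u[ok] - f1$u[ok])) / px_um, 0.1)
  expect_lt(max(abs(f2$v[ok] - f1$v[ok])) / px_um, 0.1)
})

test_that("PIV reproduces the forward displacement field of a scene", {
  sc <- make_traction_scene(n_patches = 5, extent_um = 18, cell_radius_um = 6,
                            peak_stress_pa = 500,
                            substrate = elastic_substrate(13e3), seed = 21)
  disp <- forward_displacement(sc, grid_n = 128)
  pair <- render_bead_images(sc, disp, bead_density_um2 = 1.2, seed = 13)
  f <- multipass_piv(pair$pre, pair$post, piv_config(c(64, 32, 16)),
                     pixel_size_um = pair$pixel_size_um)
  um <- cellmech:::field_matrix(disp, "u")
  vm <- cellmech:::field_matrix(disp, "v")
  h <- attr(disp, "pixel_size_um")
  tu <- cellmech:::bilinear(um, f$x / h + 0.5, f$y / h + 0.5)
  tv <- cellmech:::bilinear(vm, f$x / h + 0.5, f$y / h + 0.5)
  ff <- filter_field(f, piv_config(c(64, 32, 16)))
  ok <- !ff$outlier
  rms <- sqrt(mean(((f$u - tu)[ok])^2 + ((f$v - tv)[ok])^2))
  expect_lt(rms / pair$pixel_size_um, 0.2)
})

test_that("the filter cascade flags exactly the corrupted vectors", {
  post <- piv_pair$post
  pre <- cellmech:::shift_image(post, 2, 0)
  f <- multipass_piv(pre, post, piv_config(c(64, 32)), pixel_size_um = px_um)
  keep <- f$snr > 1.3
  # clean uniform field: nothing flagged by global/local filters
  fc <- filter_field(f, piv_config(c(64, 32), snr_threshold = 0))
  expect_false(any(fc$outlier[keep]))

  # corrupt one interior window to 10x the field magnitude
  fbad <- f
  gx <- attr(f, "grid_x")
  mid <- which(f$x == gx[5] & f$y == gx[5])
  fbad$u[mid] <- 10 * max(abs(f$u))
  fb <- filter_field(fbad, piv_config(c(64, 32), snr_threshold = 0))
  expect_true(fb$outlier[mid])

  # mask mode: windows outside the polygon are flagged
  half <- tibble::tibble(x = c(9, 18.5, 18.5, 9), y = c(-0.5, -0.5, 18.5, 18.5))
  fm <- filter_field(f, piv_config(c(64, 32), snr_threshold = 0, mask = half))
  expect_true(all(fm$outlier[fm$x < 9]))
  expect_false(any(fm$outlier[fm$x > 9 & keep & !fm$outlier]))
})

test_that("outlier interpolation fills from the nearest valid window", {
  gx <- c(1, 2, 3)
  u <- matrix(2, 3, 3); v <- matrix(1, 3, 3)
  f <- cellmech:::new_displacement_field(gx, gx, u, v, pixel_size_um = 1)
  f$outlier[5] <- TRUE  # centre window
  f$u[5] <- 99
  fi <- interpolate_outliers(f)
  expect_equal(fi$u[5], 2)
  expect_equal(fi$v[5], 1)
  expect_false(any(fi$outlier))

  # no outliers: unchanged
  expect_identical(interpolate_outliers(fi), fi)

  # tie between two donors resolves to the lowest index
  f2 <- cellmech:::new_displacement_field(c(1, 2, 3), 1, matrix(c(5, 0, 7), 1),
                                          matrix(0, 1, 3), pixel_size_um = 1)
  f2$outlier[2] <- TRUE
  expect_equal(interpolate_outliers(f2)$u[2], 5)
})
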