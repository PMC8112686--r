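# Displacement extraction from PRE/POST bead images by multi-pass windowed
# normalized cross-correlation, with the standard spurious-vector filter
# cascade and nearest-neighbour outlier replacement.
#
# Coordinate conventions: images are matrices with row = y (increasing
# downward in storage, but all coordinates are reported in um with y
# increasing with row index), col = x; pixel indices are 1-based in R,
# window centres are reported at (i + size/2 - 0.5) in 0-based pixel
# coordinates, i.e. (i + size/2 + 0.5) 1-based. Displacements are the motion
# of the PRE (deformed) pattern relative to POST (reference), in um.

#' PIV configuration
#'
#' @param window_schedule Interrogation window sizes in pixels, strictly
#'   decreasing powers of two (multi-pass refinement, coarse to fine).
#' @param overlap Window overlap fraction (0.5 by default).
#' @param snr_threshold Minimum first-to-second correlation peak ratio.
#' @param global_k Global filter: vectors further than `global_k` sd from the
#'   field mean are flagged.
#' @param local_threshold Local filter: vectors further than
#'   `local_threshold` local (3x3 neighbourhood) sd from the local median are
#'   flagged.
#' @param mask Optional polygon (tibble/data.frame with `x`, `y` in um)
#'   outside which windows are flagged (regions without fiducial markers).
#' @return A list of class `piv_config`.
#' @export
piv_config <- function(window_schedule = c(64, 32, 16), overlap = 0.5,
                       snr_threshold = 1.3, global_k = 3,
                       local_threshold = 2.5, mask = NULL) {
  check_that(all(diff(window_schedule) < 0), "window schedule must be strictly decreasing")
  check_that(all(bitwAnd(as.integer(window_schedule),
                         as.integer(window_schedule) - 1L) == 0L),
             "window sizes must be powers of 2")
  check_that(overlap >= 0 && overlap < 1, "`overlap` must be in [0, 1)")
  structure(list(window_schedule = window_schedule, overlap = overlap,
                 snr_threshold = snr_threshold, global_k = global_k,
                 local_threshold = local_threshold, mask = mask),
            class = "piv_config")
}

# Normalized cross-correlation of two equal-size windows, computed with
# zero-padded (linear) FFT correlations and per-lag overlap statistics:
# ncc(d) = cov_O(pre(.+d), post) / (sd_O(pre) sd_O(post)) over the overlap
# region O(d). The per-lag normalization is what makes the estimate
# insensitive to spots truncated by the window edges, which otherwise bias
# the interpolated peak towards zero lag. Returns the surface over lags
# |d| <= n/2, zero lag at the centre ((n/2+1, n/2+1)).
xcorr_surface <- function(pre_w, post_w) {
  n1 <- nrow(pre_w); n2 <- ncol(pre_w)
  pad <- function(m) {
    p <- matrix(0, 2 * n1, 2 * n2)
    p[seq_len(n1), seq_len(n2)] <- m
    p
  }
  corr2 <- function(fa, fb) Re(fft(fa * Conj(fb), inverse = TRUE)) / (4 * n1 * n2)
  ones <- pad(matrix(1, n1, n2))
  f1 <- fft(ones)
  fp <- fft(pad(pre_w)); fp2 <- fft(pad(pre_w^2))
  fq <- fft(pad(post_w)); fq2 <- fft(pad(post_w^2))
  nn <- corr2(f1, f1)          # overlap pixel count N(d)
  s1 <- corr2(fp, fq)          # sum pre(x+d) post(x)
  sp <- corr2(fp, f1)          # sum pre over overlap
  sq <- corr2(f1, fq)          # sum post over overlap
  spp <- corr2(fp2, f1)
  sqq <- corr2(f1, fq2)
  nn <- pmax(round(nn), 1)
  num <- s1 - sp * sq / nn
  varp <- pmax(spp - sp^2 / nn, 0)
  varq <- pmax(sqq - sq^2 / nn, 0)
  den <- sqrt(varp * varq)
  cc <- ifelse(den > 1e-9 * max(den), num / den, 0)
  ix <- function(n) c((2 * n - n / 2 + 1):(2 * n), 1:(n / 2))
  cc[ix(n1), ix(n2)]
}

# 3-point Gaussian subpixel interpolation along one axis of the peak.
gauss_subpixel <- function(cm, c0, cp) {
  if (cm > 0 && c0 > 0 && cp > 0) {
    den <- 2 * log(cm) - 4 * log(c0) + 2 * log(cp)
    if (den < 0) return((log(cm) - log(cp)) / den)
  }
  den <- 2 * (cm - 2 * c0 + cp)  # parabolic fallback
  if (den < 0) (cm - cp) / den else 0
}

# Peak location (dx, dy in px, possibly fractional) and first/second peak
# ratio of a correlation surface centred at zero displacement.
corr_peak <- function(cc, max_disp = Inf) {
  n1 <- nrow(cc); n2 <- ncol(cc)
  cy0 <- n1 / 2 + 1; cx0 <- n2 / 2 + 1
  if (is.finite(max_disp)) {
    ok_y <- abs(seq_len(n1) - cy0) <= max_disp
    ok_x <- abs(seq_len(n2) - cx0) <= max_disp
    masked <- cc
    masked[!ok_y, ] <- -Inf; masked[, !ok_x] <- -Inf
  } else masked <- cc
  pk <- arrayInd(which.max(masked), dim(cc))
  py <- pk[1]; px <- pk[2]
  peak1 <- cc[py, px]
  # second peak outside an exclusion zone wide enough to clear the main
  # peak's own shoulder (correlation peaks span ~2x the spot sigma)
  r_ex <- 3L
  excl <- masked
  excl[max(1, py - r_ex):min(n1, py + r_ex), max(1, px - r_ex):min(n2, px + r_ex)] <- -Inf
  peak2 <- max(excl)
  snr <- if (is.finite(peak2) && peak2 > 0) peak1 / peak2 else Inf
  dx <- px - cx0; dy <- py - cy0
  if (px > 1 && px < n2) dx <- dx + gauss_subpixel(cc[py, px - 1], peak1, cc[py, px + 1])
  if (py > 1 && py < n1) dy <- dy + gauss_subpixel(cc[py - 1, px], peak1, cc[py + 1, px])
  list(dx = dx, dy = dy, snr = snr, peak = peak1)
}

#' Estimate and correct rigid stage drift between PRE and POST images
#'
#' Normalized cross-correlation of a user-chosen quiet reference region (one
#' not affected by cellular traction, typically an image edge) gives the
#' rigid shift of POST relative to PRE; POST is resampled by that shift.
#'
#' @param pre,post Image matrices of equal size.
#' @param ref_region Integer vector `c(row0, col0, height, width)` (1-based)
#'   of the reference region; at least 64 x 64 px.
#' @return A list: `post_aligned` (matrix), `shift_px` = c(dx, dy) of POST
#'   relative to PRE.
#' @export
align_drift <- function(pre, post, ref_region) {
  check_that(all(dim(pre) == dim(post)), "images must have the same shape")
  r0 <- ref_region[1]; c0 <- ref_region[2]
  h <- ref_region[3]; w <- ref_region[4]
  check_that(h >= 64 && w >= 64, "reference region must be at least 64x64 px")
  check_that(r0 >= 1 && c0 >= 1 && r0 + h - 1 <= nrow(pre) && c0 + w - 1 <= ncol(pre),
             "reference region must lie inside the images")
  a <- pre[r0:(r0 + h - 1), c0:(c0 + w - 1)]
  b <- post[r0:(r0 + h - 1), c0:(c0 + w - 1)]
  check_that(sd(a) > 0 && sd(b) > 0, "flat reference region: no texture to align on")
  cc <- xcorr_surface(b, a)  # shift of POST pattern relative to PRE
  pk <- corr_peak(cc, max_disp = min(h, w) / 4)
  shifted <- shift_image(post, -pk$dx, -pk$dy)
  list(post_aligned = shifted, shift_px = c(dx = pk$dx, dy = pk$dy))
}

# Shift an image by (dx, dy) pixels with bilinear interpolation,
# edge-clamped. Positive dx moves content towards +x.
shift_image <- function(img, dx, dy) {
  nr <- nrow(img); nc <- ncol(img)
  xi <- matrix(rep(seq_len(nc), each = nr), nr, nc) - dx
  yi <- matrix(rep(seq_len(nr), times = nc), nr, nc) - dy
  matrix(bilinear(img, as.vector(xi), as.vector(yi)), nr, nc)
}

#' Select the PRE/POST plane pair carrying the largest bead displacement
#'
#' Runs a coarse single-pass PIV on every pair of planes and returns the pair
#' maximizing the mean displacement magnitude (the in-focus pair in a
#' detachment experiment). Ties break to the smallest plane indices (PRE
#' index first).
#'
#' @param pre_stack,post_stack Lists of image matrices (z-planes).
#' @param window_px Coarse interrogation window size.
#' @param pixel_size_um Pixel size, um.
#' @return A list: `pre_index`, `post_index`, `score_um` (mean displacement
#'   magnitude of the winning pair).
#' @export
select_plane_pair <- function(pre_stack, post_stack, window_px = 64,
                              pixel_size_um = 0.069) {
  check_that(length(pre_stack) >= 1 && length(post_stack) >= 1,
             "stacks must contain at least one plane")
  best <- c(NA_integer_, NA_integer_); best_score <- -Inf
  for (i in seq_along(pre_stack)) {
    for (j in seq_along(post_stack)) {
      f <- multipass_piv(pre_stack[[i]], post_stack[[j]],
                         piv_config(window_schedule = window_px),
                         pixel_size_um = pixel_size_um)
      score <- mean(sqrt(f$u^2 + f$v^2))
      if (score > best_score) { best_score <- score; best <- c(i, j) }
    }
  }
  list(pre_index = best[1], post_index = best[2], score_um = best_score)
}

#' Multi-pass PIV displacement field
#'
#' Windowed FFT cross-correlation between PRE (deformed) and POST (reference)
#' images over a regular grid of interrogation windows, refined over the
#' window schedule: each pass seeds the next with its (integer-rounded)
#' displacement predictor, so the final small windows only resolve the
#' residual. Subpixel peak position by 3-point Gaussian interpolation; the
#' per-window signal-to-noise ratio is the first-to-second peak ratio.
#'
#' @param pre,post Image matrices of equal size, drift-aligned.
#' @param config A [piv_config()].
#' @param pixel_size_um Pixel size, um/px.
#' @return A `displacement_field` tibble (`x`, `y` um; `u`, `v` um; `snr`;
#'   `outlier`, all FALSE here) on the final-pass window grid.
#' @export
multipass_piv <- function(pre, post, config = piv_config(),
                          pixel_size_um = 0.069) {
  check_that(all(dim(pre) == dim(post)), "images must have the same shape")
  check_that(max(config$window_schedule) <= min(dim(pre)),
             "window larger than image")
  pred <- NULL  # list(gx, gy, u, v) from previous pass, in px
  for (ws in config$window_schedule) {
    pred <- piv_pass(pre, post, ws, config$overlap, pred)
  }
  new_displacement_field(
    x = (pred$gx - 0.5) * pixel_size_um, y = (pred$gy - 0.5) * pixel_size_um,
    u = pred$u * pixel_size_um, v = pred$v * pixel_size_um,
    snr = pred$snr, outlier = matrix(FALSE, length(pred$gy), length(pred$gx)),
    pixel_size_um = pixel_size_um,
    window_size_px = min(config$window_schedule), overlap = config$overlap)
}

# One correlation pass at window size ws. `pred` carries the previous-pass
# field for predictor offsets. Grid coordinates in 1-based px centres.
piv_pass <- function(pre, post, ws, overlap, pred = NULL) {
  nr <- nrow(pre); nc <- ncol(pre)
  step <- max(1L, round(ws * (1 - overlap)))
  x0 <- seq(1L, nc - ws + 1L, by = step)
  y0 <- seq(1L, nr - ws + 1L, by = step)
  gx <- x0 + ws / 2 - 0.5  # 1-based window centre
  gy <- y0 + ws / 2 - 0.5
  u <- matrix(0, length(y0), length(x0))
  v <- u; snr <- u
  for (iy in seq_along(y0)) {
    for (ix in seq_along(x0)) {
      off <- c(0L, 0L)
      if (!is.null(pred)) {
        pu <- bilinear(pred$u, approx_index(pred$gx, gx[ix]),
                       approx_index(pred$gy, gy[iy]))
        pv <- bilinear(pred$v, approx_index(pred$gx, gx[ix]),
                       approx_index(pred$gy, gy[iy]))
        off <- c(round(pu), round(pv))
      }
      # PRE window shifted by the predictor so the residual is small
      px0 <- x0[ix] + off[1]; py0 <- y0[iy] + off[2]
      px0 <- min(max(px0, 1L), nc - ws + 1L)
      py0 <- min(max(py0, 1L), nr - ws + 1L)
      applied <- c(px0 - x0[ix], py0 - y0[iy])
      wp <- pre[py0:(py0 + ws - 1L), px0:(px0 + ws - 1L)]
      wq <- post[y0[iy]:(y0[iy] + ws - 1L), x0[ix]:(x0[ix] + ws - 1L)]
      if (sd(wp) == 0 || sd(wq) == 0) {
        u[iy, ix] <- applied[1]; v[iy, ix] <- applied[2]; snr[iy, ix] <- 0
        next
      }
      pk <- corr_peak(xcorr_surface(wp, wq), max_disp = ws / 3)
      u[iy, ix] <- applied[1] + pk$dx
      v[iy, ix] <- applied[2] + pk$dy
      snr[iy, ix] <- pk$snr
    }
  }
  list(gx = gx, gy = gy, u = u, v = v, snr = snr)
}

# Fractional index of position p in strictly increasing grid g.
approx_index <- function(g, p) {
  if (length(g) == 1) return(1)
  i <- approx(g, seq_along(g), xout = p, rule = 2)$y
  i
}

#' Flag spurious displacement vectors
#'
#' Applies the filter cascade: (i) SNR filter — windows whose correlation
#' first-to-second peak ratio falls below the threshold; (ii) global filter —
#' vectors further than `global_k` sd from the field mean (per component);
#' (iii) local filter — vectors further than `local_threshold` local sd from
#' the 3x3 neighbourhood median; (iv) mask mode — windows outside the
#' supplied polygon. Flags are OR-ed into `outlier`.
#'
#' @param field A `displacement_field` from [multipass_piv()].
#' @param config A [piv_config()] (thresholds and optional mask polygon).
#' @return The field with `outlier` set.
#' @export
filter_field <- function(field, config = piv_config()) {
  u <- field_matrix(field, "u"); v <- field_matrix(field, "v")
  snr <- field_matrix(field, "snr")
  bad <- snr < config$snr_threshold
  # deviations below ~0.05 px are within correlation-peak accuracy and are
  # never outliers, whatever the field statistics
  floor_um <- 0.05 * (attr(field, "pixel_size_um") %||% 0.069)
  for (comp in list(u, v)) {
    mu <- mean(comp); s <- sd(comp)
    if (is.finite(s) && s > 0)
      bad <- bad | (abs(comp - mu) > pmax(config$global_k * s, floor_um))
  }
  med_u <- neighborhood_stat(u, median); med_v <- neighborhood_stat(v, median)
  sd_u <- neighborhood_stat(u, sd); sd_v <- neighborhood_stat(v, sd)
  bad <- bad |
    abs(u - med_u) > pmax(config$local_threshold * sd_u, floor_um) |
    abs(v - med_v) > pmax(config$local_threshold * sd_v, floor_um)
  if (!is.null(config$mask)) {
    gx <- attr(field, "grid_x"); gy <- attr(field, "grid_y")
    inside <- point_in_polygon(rep(gx, each = length(gy)),
                               rep(gy, times = length(gx)),
                               config$mask$x, config$mask$y)
    bad <- bad | !matrix(inside, length(gy), length(gx))
  }
  check_that(!all(bad), "all windows flagged as outliers; field unrecoverable")
  out <- field
  out$outlier <- as.vector(bad)
  out
}

# Apply stat over the 3x3 neighbourhood of each entry, excluding the centre.
neighborhood_stat <- function(m, stat) {
  nr <- nrow(m); nc <- ncol(m)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      ri <- max(1, i - 1):min(nr, i + 1)
      cj <- max(1, j - 1):min(nc, j + 1)
      vals <- m[ri, cj]
      vals <- vals[-(which(ri == i) + (which(cj == j) - 1) * length(ri))]
      out[i, j] <- stat(vals)
    }
  }
  out
}

# Even-odd rule point-in-polygon test, vectorized over points.
point_in_polygon <- function(px, py, vx, vy) {
  n <- length(vx)
  inside <- rep(FALSE, length(px))
  j <- n
  for (i in seq_len(n)) {
    cross <- (vy[i] > py) != (vy[j] > py)
    xint <- (vx[j] - vx[i]) * (py - vy[i]) / (vy[j] - vy[i]) + vx[i]
    inside <- xor(inside, cross & (px < xint))
    j <- i
  }
  inside
}

#' Replace flagged outlier vectors by their nearest valid neighbour
#'
#' Each flagged window receives the (u, v) of the nearest (Euclidean distance
#' in grid coordinates) non-flagged window; ties break to the lowest grid
#' index (column-major order). The result has no remaining outliers.
#'
#' @param field A `displacement_field` with `outlier` set by [filter_field()].
#' @return The completed field (`outlier` all FALSE).
#' @export
interpolate_outliers <- function(field) {
  bad <- field$outlier
  if (!any(bad)) return(field)
  check_that(!all(bad), "no valid windows to interpolate from")
  good_idx <- which(!bad)
  xs <- field$x; ys <- field$y
  out <- field
  for (i in which(bad)) {
    d2 <- (xs[good_idx] - xs[i])^2 + (ys[good_idx] - ys[i])^2
    donor <- good_idx[which.min(d2)]  # first minimum = lowest index on ties
    out$u[i] <- field$u[donor]
    out$v[i] <- field$v[donor]
  }
  out$outlier <- FALSE
  out
}
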