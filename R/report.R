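# Joining traction summaries with binding-kinetics fits: cellular- and
# subcellular-level correlation between traction and residence time, the
# rank-based group comparison used for condition contrasts, and an
# end-to-end synthetic study driver.

#' Correlate residence time with traction
#'
#' Ordinary least-squares line plus Pearson correlation for paired
#' measurements at either the cellular level (one point per cell, different
#' substrate stiffness) or the subcellular level (one point per
#' focal-adhesion region of one or more cells on the same substrate).
#'
#' @param data A data frame holding the paired values.
#' @param x,y Column names (strings) of predictor and response, e.g.
#'   `"t_res_s"` and `"t_mean_pa"`.
#' @param level `"cellular"` or `"subcellular"` (annotation only).
#' @param weights Optional column name of weights for a weighted fit
#'   (unweighted by default).
#' @return A `mech_correlation`: list with `slope`, `slope_se`, `intercept`,
#'   `intercept_se`, `r`, `n`, `level`, `data`.
#' @export
#' @examples
#' d <- tibble::tibble(t_res_s = c(27, 30, 32), t_mean_pa = c(40, 90, 110))
#' correlate_mech(d, "t_res_s", "t_mean_pa", level = "cellular")$r
correlate_mech <- function(data, x, y, level = c("cellular", "subcellular"),
                           weights = NULL) {
  level <- match.arg(level)
  xs <- data[[x]]; ys <- data[[y]]
  keep <- is.finite(xs) & is.finite(ys)
  xs <- xs[keep]; ys <- ys[keep]
  check_that(length(xs) >= 3, "need >= 3 paired finite values")
  check_that(sd(xs) > 0, "zero variance in `%s`", x)
  w <- if (!is.null(weights)) data[[weights]][keep] else NULL
  fit <- if (is.null(w)) lm(ys ~ xs) else lm(ys ~ xs, weights = w)
  # exact collinear input is legitimate here; summary.lm warns about it
  cf <- suppressWarnings(summary(fit)$coefficients)
  r <- if (sd(ys) > 0) cor(xs, ys) else 0
  structure(list(slope = cf[2, 1], slope_se = cf[2, 2],
                 intercept = cf[1, 1], intercept_se = cf[1, 2],
                 r = r, n = length(xs), level = level,
                 data = tibble::tibble(x = xs, y = ys)),
            class = "mech_correlation")
}

#' @export
print.mech_correlation <- function(x, ...) {
  cat(sprintf("<mech_correlation> %s level: slope %.4g +/- %.2g, r = %.3f (n = %d)\n",
              x$level, x$slope, x$slope_se, x$r, x$n))
  invisible(x)
}

#' @export
tidy.mech_correlation <- function(x, ...) {
  tibble::tibble(term = c("intercept", "slope"),
                 estimate = c(x$intercept, x$slope),
                 std.error = c(x$intercept_se, x$slope_se))
}

#' @export
glance.mech_correlation <- function(x, ...) {
  tibble::tibble(slope = x$slope, slope_se = x$slope_se, intercept = x$intercept,
                 r = x$r, n = x$n, level = x$level)
}

#' Rank-sum comparison of two condition groups
#'
#' Two-sided Mann-Whitney (Wilcoxon rank-sum) test: exact distribution when
#' both groups have 12 or fewer observations and there are no ties, normal
#' approximation with tie correction otherwise.
#'
#' @param a,b Numeric samples (each n >= 2).
#' @return A tibble: `statistic` (U), `p_value`, `method`, `flag` (e.g. all
#'   values tied).
#' @export
#' @examples
#' compare_groups(c(1, 2, 3), c(10, 11, 12))
compare_groups <- function(a, b) {
  check_that(length(a) >= 2 && length(b) >= 2, "each sample needs >= 2 values")
  if (length(unique(c(a, b))) == 1L) {
    return(tibble::tibble(statistic = length(a) * length(b) / 2, p_value = 1,
                          method = "degenerate", flag = "all values tied"))
  }
  exact <- length(a) <= 12 && length(b) <= 12 && !any(duplicated(c(a, b)))
  wt <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact, correct = !exact))
  tibble::tibble(statistic = unname(wt$statistic), p_value = wt$p.value,
                 method = if (exact) "exact" else "normal approximation",
                 flag = NA_character_)
}

#' Simulate one complete multi-parametric single-cell experiment
#'
#' Generates a traction scene, its forward displacement field, reconstructs
#' traction by regularized Fourier inversion, picks focal-adhesion regions at
#' the patch locations, and simulates a photobleaching trace per region with
#' a residence time linearly coupled to the region's reconstructed traction
#' (`t_res = t_res_base + coupling * T_region`), emulating the observed
#' force-sensitivity of adhesion-protein unbinding.
#'
#' @param e_pa Substrate Young's modulus, Pa.
#' @param n_regions Number of probed adhesion regions (patches used as
#'   region centres).
#' @param t_res_base_s,coupling_s_per_pa Linear coupling of residence time to
#'   regional traction.
#' @param frap_noise_sd Intensity noise sd of the simulated traces.
#' @param grid_n Reconstruction grid (per side).
#' @param lambda Regularization; `NULL` selects by L-curve.
#' @param seed Integer seed.
#' @return A list of class `mech_cell`: `scene`, `displacement`, `traction`,
#'   `cell` (one-row tibble), `regions` (tibble with ground-truth and fitted
#'   kinetics per region).
#' @export
simulate_cell_experiment <- function(e_pa = 3.4e3, n_regions = 4,
                                     t_res_base_s = 20, coupling_s_per_pa = 0.05,
                                     frap_noise_sd = 5, grid_n = 64,
                                     lambda = 0, seed = 1L) {
  scene <- make_traction_scene(
    n_patches = max(n_regions, 6), peak_stress_pa = 300,
    extent_um = 48, cell_radius_um = 12,
    substrate = elastic_substrate(e_pa), seed = seed)
  disp <- forward_displacement(scene, grid_n = grid_n)
  if (is.null(lambda)) lambda <- select_lambda(disp, scene$substrate)$lambda_opt
  trac <- fttc_inverse(disp, scene$substrate, lambda = lambda)
  cellsum <- summarize_cell(disp, trac, scene$boundary)
  centers <- scene$patches[seq_len(n_regions), c("x", "y")]
  regions <- region_average_traction(trac, centers)
  set.seed(seed + 1000L)
  seeds <- sample.int(1e6, n_regions)
  kin <- purrr::map_dfr(seq_len(n_regions), function(i) {
    t_res_true <- t_res_base_s + coupling_s_per_pa * regions$t_region_pa[i]
    k_true <- 1 / t_res_true
    trc <- gen_frap_trace(k_off = k_true, m = 0.5, noise_sd = frap_noise_sd,
                          seed = seeds[i])
    fit <- fit_recovery(normalize_frap(trc))
    tibble::tibble(k_off_true = k_true, t_res_true_s = t_res_true,
                   k_off = fit$k_off, k_off_se = fit$k_off_se,
                   t_res_s = fit$t_res_s, t_res_se = fit$t_res_se)
  })
  cell <- tibble::tibble(
    e_kpa = e_pa / 1e3, area_um2 = cellsum$area_um2,
    d_mean_um = cellsum$d_mean_um, t_mean_pa = cellsum$t_mean_pa,
    f_total_nn = cellsum$f_total_nn, seed = seed)
  structure(list(scene = scene, displacement = disp, traction = trac,
                 cell = cell,
                 regions = dplyr::bind_cols(regions, kin)),
            class = "mech_cell")
}

#' Build the joined study report
#'
#' Joins per-cell traction summaries with per-region kinetics, computes the
#' cellular-level and subcellular-level correlations, and returns
#' reproducible tables (byte-identical for identical inputs).
#'
#' @param cells Tibble with one row per cell: `cell_id`, `e_kpa`,
#'   `d_mean_um`, `t_mean_pa`, `f_total_nn`, and optionally `t_res_s` (mean
#'   residence time of the cell's condition).
#' @param regions Tibble with one row per probed region: `cell_id`,
#'   `t_region_pa`, `t_res_s` (+ optional SEs).
#' @return A list of class `mech_report`: `cells`, `regions` (joined,
#'   regions without kinetics listed in `excluded`), `cellular`
#'   (`mech_correlation` or NULL when < 3 cells carry `t_res_s`),
#'   `subcellular` (`mech_correlation`).
#' @export
build_report <- function(cells, regions) {
  check_that(nrow(cells) >= 1, "no cells to report")
  missing_kin <- regions[!is.finite(regions$t_res_s) | !is.finite(regions$t_region_pa), ]
  good <- regions[is.finite(regions$t_res_s) & is.finite(regions$t_region_pa), ]
  joined <- dplyr::inner_join(
    good, dplyr::select(cells, dplyr::any_of(c("cell_id", "e_kpa"))), by = "cell_id")
  cellular <- NULL
  if ("t_res_s" %in% names(cells) && sum(is.finite(cells$t_res_s)) >= 3) {
    cellular <- correlate_mech(cells[is.finite(cells$t_res_s), ],
                               "t_res_s", "t_mean_pa", "cellular")
  }
  subcellular <- if (nrow(joined) >= 3)
    correlate_mech(joined, "t_res_s", "t_region_pa", "subcellular") else NULL
  structure(list(cells = cells, regions = joined, excluded = missing_kin,
                 cellular = cellular, subcellular = subcellular),
            class = "mech_report")
}

#' @export
print.mech_report <- function(x, ...) {
  cat(sprintf("<mech_report> %d cells, %d regions (%d excluded)\n",
              nrow(x$cells), nrow(x$regions), nrow(x$excluded)))
  if (!is.null(x$cellular)) print(x$cellular)
  if (!is.null(x$subcellular)) print(x$subcellular)
  invisible(x)
}
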