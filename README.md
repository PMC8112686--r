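# cellmech

An integrated R pipeline for multi-parametric single-cell mechanics on
elastic substrates. Adherent cells pull on their surroundings through focal
adhesions, and both the magnitude of that traction and the binding kinetics
of adhesion proteins (zyxin in particular) respond to substrate stiffness.
`cellmech` implements every quantitative step needed to measure this on one
cell — and to ask whether regions that pull harder hold their adhesion
proteins longer:

* **AFM elasticity** — substrate Young's modulus from force–distance
  curves via contact-point detection and the Sneddon cone-contact model
  `F = (2/π)·E/(1−ν²)·tan(α)·δ²`, with per-experiment aggregation.
* **Deformation maps** — substrate displacement from PRE/POST fiducial-bead
  images by multi-pass windowed normalized cross-correlation (64→32→16 px,
  50 % overlap), sub-pixel Gaussian peak interpolation, SNR/global/local/mask
  outlier filters and nearest-neighbour replacement, plus drift alignment
  and z-plane pair selection.
* **Traction reconstruction** — Fourier-transform traction cytometry on the
  elastic half-space Green's tensor with zeroth-order Tikhonov
  regularization, `T̂(k) = (GᵀG + λ²I)⁻¹ Gᵀ û(k)`, the L-curve
  maximum-curvature criterion for λ, cell masks (Otsu or polygon), and
  cellular (`D`, `T`, `F = T·A`) and ~20 µm² region summaries.
* **FCS** — sub-record-averaged intensity autocorrelation, 1-/2-component
  3D-diffusion fits `G(τ) = Σ G₀ᵢ (1+τ/τ_Dᵢ)⁻¹ (1+τ/(ω²τ_Dᵢ))^(−1/2)`,
  detection-volume calibration, and `D = w_r²/(4τ_D)`.
* **FRAP** — double-normalized recovery curves and the reaction-dominant
  fit `F(t) = m·(1−exp(−k_off·t))`, residence time `t_res = 1/k_off`.
* **Correlation report** — joins traction with kinetics at cellular and
  subcellular level (OLS slope, Pearson r) and Mann–Whitney group
  comparisons (exact for small groups).
* **Synthetic data** — seeded generators for every modality (traction
  scenes → displacement fields → bead images, force curves, FRAP traces,
  Brownian-dynamics FCS traces), so the whole pipeline is testable without
  raw microscopy data.

All user-facing functions take and return tibbles (fields are tidy tables
with grid attributes), fitted objects have `tidy()`/`glance()` methods, and
each result type has an `autoplot()`.

## Worked example

One synthetic cell, end to end — scene → forward displacement → traction
reconstruction → region tractions → FRAP fits, with residence time coupled
to regional traction:

```r
library(cellmech)

# substrate stiffness from a (noisy synthetic) AFM curve
fc  <- gen_force_curve(13e3, alpha_rad = 20 * pi / 180, noise_sd_nn = 0.2, seed = 1)
fit_sneddon(fc, find_contact_point(fc))
#> <elasticity_fit> E = 12.9 +/- 0.16 kPa (contact 503 nm, 319 pts)

cell <- simulate_cell_experiment(e_pa = 3.4e3, n_regions = 4,
                                 coupling_s_per_pa = 0.3, seed = 2)
cell$cell
#> # A tibble: 1 × 6
#>   e_kpa area_um2 d_mean_um t_mean_pa f_total_nn  seed
#> 1   3.4     455.    0.0217      8.59       3.91     2
dplyr::select(cell$regions, region, t_region_pa, t_res_s, t_res_true_s)
#> # A tibble: 4 × 4
#>   region t_region_pa t_res_s t_res_true_s
#> 1      1        28.6    30.2         28.6
#> 2      2        57.4    34.4         37.2
#> 3      3        50.2    30.3         35.1
#> 4      4        48.2    33.6         34.4
```

The cell pulls with a mean traction of 8.6 Pa over its 455 µm² footprint
(total force 3.9 nN); the four probed focal-adhesion regions carry 29–57 Pa
locally, and the fitted zyxin residence times (30–34 s) track the
generating values within the FRAP noise. Joining three such cells
reproduces the subcellular traction–residence-time coupling:

```r
cells   <- purrr::map(1:3, ~ simulate_cell_experiment(
  seed = .x, n_regions = 4, coupling_s_per_pa = 0.3))
regions <- purrr::imap_dfr(cells, ~ dplyr::mutate(.x$regions, cell_id = .y))
cell_tb <- purrr::imap_dfr(cells, ~ dplyr::mutate(.x$cell,    cell_id = .y))
build_report(cell_tb, regions)$subcellular
#> <mech_correlation> subcellular level: slope 1.896 +/- 0.32, r = 0.880 (n = 12)
```

Regions that exert more traction show longer residence times (slope
1.9 Pa/s, r = 0.88 across 12 regions) — the qualitative signature the
combined TFM+FRAP analysis is designed to detect.

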