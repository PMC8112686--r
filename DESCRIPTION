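Package: cellmech
Title: Multi-Parametric Single-Cell Mechanics from Traction Microscopy,
    AFM, FRAP and FCS
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An integrated analysis pipeline for multi-parametric live-cell
    mechanics experiments on elastic polyacrylamide substrates. Estimates
    substrate Young's modulus from AFM force-distance curves with the Sneddon
    cone-contact model, extracts substrate deformation fields from fiducial
    bead image pairs by multi-pass cross-correlation particle image
    velocimetry, reconstructs cellular traction by regularized Fourier-transform
    traction cytometry with L-curve selection of the Tikhonov parameter,
    quantifies focal-adhesion protein diffusion from fluorescence correlation
    spectroscopy autocorrelation curves and unbinding kinetics from
    fluorescence recovery after photobleaching, and joins the results into
    cellular- and subcellular-level correlations between traction and protein
    residence time. A seeded synthetic-data generator produces ground-truth
    scenes for every stage so the whole pipeline is testable without raw
    microscopy data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    graphics,
    ggplot2,
    minpack.lm,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    tiff,
    withr,
    knitr
Config/testthat/edition: 3
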