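# ggplot2 visualisations for each result type.

#' @export
autoplot.displacement_field <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$mag <- sqrt(df$u^2 + df$v^2)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$mag)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "|U| (µm)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Substrate deformation")
}

#' @export
autoplot.traction_field <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, fill = .data$t_mag)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(option = "inferno", name = "|T| (Pa)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)",
                  title = "Reconstructed traction")
}

#' @export
autoplot.lcurve_result <- function(object, ...) {
  ggplot2::ggplot(object$table, ggplot2::aes(x = .data$rho, y = .data$eta)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(data = object$table[object$table$lambda == object$lambda_opt, ],
                        colour = "red", size = 3) +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "residual norm", y = "solution norm",
                  title = sprintf("L-curve (lambda_opt = %.3g)", object$lambda_opt))
}

#' @export
autoplot.acf_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$tau_s, y = .data$g)) +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = expression(tau ~ "(s)"), y = expression(G(tau)),
                  title = "Intensity autocorrelation")
}

#' @export
autoplot.recovery_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$t_s, y = .data$f)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "time after bleach (s)", y = "normalized recovery F(t)",
                  title = "FRAP recovery")
}

#' @export
autoplot.force_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$z_nm, y = .data$force_nn)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "z (nm)", y = "force (nN)", title = "AFM force curve")
}

#' @export
autoplot.mech_correlation <- function(object, ...) {
  xlab <- "residence time (s)"
  ylab <- "traction (Pa)"
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = object$slope, intercept = object$intercept,
                         colour = "red") +
    ggplot2::labs(x = xlab, y = ylab,
                  title = sprintf("%s-level correlation (r = %.2f, n = %d)",
                                  object$level, object$r, object$n))
}
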