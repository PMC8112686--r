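# CSV readers/writers for the gridded field containers. Coordinates are
# window/grid centres in um, x = column direction, y = row direction
# (y increases with row index); displacements in um, tractions in Pa.

#' Write a displacement field to CSV
#'
#' Columns `x_um,y_um,u_um,v_um,snr,outlier`.
#'
#' @param field A `displacement_field`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_displacement_field <- function(field, path) {
  readr::write_csv(tibble::tibble(
    x_um = field$x, y_um = field$y, u_um = field$u, v_um = field$v,
    snr = field$snr, outlier = field$outlier), path)
  invisible(path)
}

#' Read a displacement field from CSV
#'
#' Inverse of [write_displacement_field()]; the grid must be complete and
#' regular.
#'
#' @param path CSV path with columns `x_um,y_um,u_um,v_um[,snr,outlier]`.
#' @return A `displacement_field` tibble.
#' @export
read_displacement_field <- function(path) {
  tb <- readr::read_csv(path, show_col_types = FALSE)
  gx <- sort(unique(tb$x_um)); gy <- sort(unique(tb$y_um))
  check_that(nrow(tb) == length(gx) * length(gy), "incomplete displacement grid")
  tb <- tb[order(tb$x_um, tb$y_um), ]
  new_displacement_field(
    gx, gy,
    matrix(tb$u_um, length(gy), length(gx)),
    matrix(tb$v_um, length(gy), length(gx)),
    snr = if ("snr" %in% names(tb)) matrix(tb$snr, length(gy), length(gx)) else NULL,
    outlier = if ("outlier" %in% names(tb))
      matrix(tb$outlier, length(gy), length(gx)) else NULL,
    pixel_size_um = gx[2] - gx[1])
}

#' Write a traction field to CSV
#'
#' Columns `x_um,y_um,tx_pa,ty_pa,t_mag_pa`.
#'
#' @param field A `traction_field`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_traction_field <- function(field, path) {
  readr::write_csv(tibble::tibble(
    x_um = field$x, y_um = field$y, tx_pa = field$tx, ty_pa = field$ty,
    t_mag_pa = field$t_mag), path)
  invisible(path)
}

#' Read a single-plane TIFF image as a matrix
#'
#' @param path TIFF file.
#' @return Numeric matrix (row = y, col = x).
#' @export
read_image_tiff <- function(path) {
  check_that(requireNamespace("tiff", quietly = TRUE),
             "the 'tiff' package is required to read TIFF files")
  img <- tiff::readTIFF(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  img
}
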