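#' Write a calibrated slice as 16-bit TIFF with a JSON sidecar
#'
#' Grey values are stored as 16-bit TIFF (scaled to the 0..65535 range);
#' the pixel spacing, display window and any ground truth travel in a JSON
#' sidecar at \code{<path>.json}.
#'
#' @param slice an \code{\link{image_slice}}.
#' @param path output TIFF path.
#' @param ground_truth optional list stored verbatim in the sidecar.
#' @return \code{path}, invisibly.
#' @export
write_slice <- function(slice, path, ground_truth = NULL) {
  stopifnot(inherits(slice, "image_slice"))
  tiff::writeTIFF(pmin(pmax(slice$pixels / 65535, 0), 1), path,
                  bits.per.sample = 16L)
  side <- list(pixel_spacing_mm = slice$pixel_spacing,
               window = list(wl = slice$wl, ww = slice$ww))
  if (!is.null(ground_truth)) side$ground_truth <- ground_truth
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a slice written by \code{\link{write_slice}}
#'
#' @param path TIFF path (sidecar expected at \code{<path>.json}).
#' @return An \code{\link{image_slice}}; any stored ground truth is attached
#'   as attribute \code{"ground_truth"}.
#' @export
read_slice <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  px <- tiff::readTIFF(path) * 65535
  out <- image_slice(px, side$pixel_spacing_mm,
                     wl = side$window$wl, ww = side$window$ww)
  if (!is.null(side$ground_truth))
    attr(out, "ground_truth") <- side$ground_truth
  out
}

#' Write a two-channel stack as multi-page TIFF with a JSON sidecar
#'
#' Pages are channel-interleaved (green then red within each z plane).
#' Intensities are scaled by the stack maximum for 16-bit storage; the scale
#' is recorded in the sidecar.
#'
#' @param stack a \code{"fluor_stack"}.
#' @param path output TIFF path.
#' @return \code{path}, invisibly.
#' @export
write_stack <- function(stack, path) {
  stopifnot(inherits(stack, "fluor_stack"))
  mx <- max(stack$green, stack$red, 1e-12)
  nz <- dim(stack$green)[3]
  pages <- vector("list", 2L * nz)
  for (z in seq_len(nz)) {
    pages[[2L * z - 1L]] <- stack$green[, , z] / mx
    pages[[2L * z]] <- stack$red[, , z] / mx
  }
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(voxel_size_um = stack$voxel_size,
               channels = c("green", "red"), n_z = nz,
               intensity_scale = mx)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a stack written by \code{\link{write_stack}}
#'
#' @param path TIFF path (sidecar expected at \code{<path>.json}).
#' @return A \code{"fluor_stack"} (without ground truth).
#' @export
read_stack <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  nz <- side$n_z
  d <- dim(pages[[1]])
  green <- array(0, c(d[1], d[2], nz))
  red <- array(0, c(d[1], d[2], nz))
  for (z in seq_len(nz)) {
    green[, , z] <- pages[[2L * z - 1L]] * side$intensity_scale
    red[, , z] <- pages[[2L * z]] * side$intensity_scale
  }
  structure(list(green = green, red = red,
                 voxel_size = side$voxel_size_um, truth = NULL),
            class = "fluor_stack")
}

#' Write / read a plate or biomarker table as CSV
#'
#' Thin wrappers around \code{\link[utils]{write.csv}} /
#' \code{\link[utils]{read.csv}} fixing the conventions used throughout the
#' package (header row, no row names, strings kept as character).
#'
#' @param table a data.frame.
#' @param path CSV path.
#' @return \code{write_table_csv}: \code{path} invisibly;
#'   \code{read_table_csv}: a data.frame.
#' @export
write_table_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_table_csv
#' @export
read_table_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}
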