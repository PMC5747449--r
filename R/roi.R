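#' Statistics over a circular well ROI
#'
#' Mean, SD and pixel count over all pixels whose centre lies inside the
#' circle. Used to quantify the MRI signal of agarose-well phantoms.
#'
#' @param slice an \code{\link{image_slice}}.
#' @param center (x, y) centre in pixel coordinates (1-based).
#' @param radius_mm circle radius in mm, > 0; the ROI must lie fully inside
#'   the image.
#' @return List with \code{mean}, \code{sd}, \code{n_pixels}
#'   (\code{sd} is \code{NA} for a single pixel).
#' @export
roi_stats <- function(slice, center, radius_mm) {
  stopifnot(inherits(slice, "image_slice"))
  if (!is.numeric(radius_mm) || radius_mm <= 0)
    stop("radius must be positive")
  r_px <- radius_mm / slice$pixel_spacing
  px <- slice$pixels
  if (center[1] - r_px < 0.5 || center[1] + r_px > ncol(px) + 0.5 ||
      center[2] - r_px < 0.5 || center[2] + r_px > nrow(px) + 0.5)
    stop("ROI extends outside the image")
  cols <- seq_len(ncol(px))
  rows <- seq_len(nrow(px))
  inside <- outer((rows - center[2])^2, (cols - center[1])^2, "+") <= r_px^2
  vals <- px[inside]
  if (length(vals) == 0L) {
    # radius smaller than half a pixel: fall back to the nearest pixel
    vals <- px[round(center[2]), round(center[1])]
  }
  list(mean = mean(vals),
       sd = if (length(vals) > 1L) sd(vals) else NA_real_,
       n_pixels = length(vals))
}

#' Minimum concentration producing marked hypointense signal
#'
#' Scans an ascending concentration series of well ROI means against a
#' control (water / agarose) ROI and returns the smallest concentration
#' \code{c} such that every concentration at or above \code{c} has a well
#' mean at or below \code{control_mean - k * control_sd} ("at or above"
#' semantics). \code{NA} when no concentration qualifies.
#'
#' @param concentrations strictly increasing concentrations (ug/mL).
#' @param well_means ROI mean grey value per concentration.
#' @param control_mean,control_sd control-region statistics
#'   (\code{control_sd >= 0}).
#' @param k hypointensity margin in control SDs (default 3).
#' @return The threshold concentration, or \code{NA_real_} if none.
#' @export
detect_threshold_concentration <- function(concentrations, well_means,
                                           control_mean, control_sd, k = 3) {
  if (length(concentrations) == 0L) stop("empty concentration series")
  if (length(concentrations) != length(well_means))
    stop("concentrations/well_means length mismatch")
  if (any(diff(concentrations) <= 0))
    stop("concentrations must be strictly increasing")
  if (control_sd < 0) stop("control SD must be non-negative")
  cutoff <- control_mean - k * control_sd
  dark <- well_means <= cutoff
  # smallest index from which all subsequent wells are dark
  ok <- rev(cumprod(rev(dark))) > 0
  if (!any(ok)) return(NA_real_)
  concentrations[which(ok)[1]]
}
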