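#' Mean percent discrepancy of an ICP-OES calibration series
#'
#' Compares observed elemental-Fe concentrations against the expected values
#' of a dilution series and returns the mean per-pair percent discrepancy
#' \code{100 * (expected - observed) / expected}. Used to estimate the
#' fraction of nanoparticle mass lost during filtration.
#'
#' @param expected numeric vector of expected concentrations (ug/mL), all > 0.
#' @param observed numeric vector of observed concentrations (ug/mL), same
#'   length as \code{expected}, all >= 0.
#' @return Mean percent discrepancy (a single number, in percent).
#' @examples
#' mean_percent_discrepancy(40, 20.3)   # single dosing-sample pair
#' @export
mean_percent_discrepancy <- function(expected, observed) {
  stopifnot(length(expected) == length(observed), length(expected) >= 1L)
  if (any(!is.finite(expected)) || any(expected <= 0))
    stop("all expected concentrations must be positive")
  if (any(!is.finite(observed)) || any(observed < 0))
    stop("observed concentrations must be non-negative")
  mean(100 * (expected - observed) / expected)
}

#' Adjust a nominal dose for filtration loss
#'
#' @param nominal nominal dose (mass in ug or concentration in ug/mL).
#' @param loss_fraction fraction of mass lost, in `[0, 1)`.
#' @return Adjusted dose \code{nominal * (1 - loss_fraction)}.
#' @examples
#' adjust_dose(40, 0.44)  # 22.4
#' @export
adjust_dose <- function(nominal, loss_fraction) {
  if (!is.numeric(loss_fraction) || length(loss_fraction) != 1L ||
      !is.finite(loss_fraction) || loss_fraction < 0 || loss_fraction >= 1)
    stop("loss_fraction must lie in [0, 1)")
  nominal * (1 - loss_fraction)
}

#' Exposure concentration of a dose in culture media
#'
#' @param dose_mass dose mass (ug).
#' @param media_volume media volume (mL), > 0.
#' @param signif_digits significant figures for reporting (default 3,
#'   matching the convention of printed exposure concentrations).
#' @return Concentration in ug/mL, rounded to \code{signif_digits}
#'   significant figures.
#' @examples
#' exposure_concentration(560, 9)  # 62.2
#' @export
exposure_concentration <- function(dose_mass, media_volume, signif_digits = 3) {
  if (!is.numeric(media_volume) || any(media_volume <= 0))
    stop("media_volume must be positive")
  signif(dose_mass / media_volume, signif_digits)
}

#' Summarise a particle-diameter sample
#'
#' Histogram (fixed bin width), arithmetic mean and modal bin centre for a
#' set of particle diameters, e.g. from TEM sizing.
#'
#' @param diameters numeric vector of diameters (nm), all > 0.
#' @param bin_width histogram bin width (nm), > 0.
#' @return A list of class \code{"size_summary"} with elements
#'   \code{n}, \code{mean}, \code{breaks}, \code{counts}, \code{mids},
#'   \code{modal_bin_center}.
#' @export
size_summary <- function(diameters, bin_width = 1) {
  if (length(diameters) < 1L) stop("need at least one diameter")
  if (any(!is.finite(diameters)) || any(diameters <= 0))
    stop("diameters must be positive")
  if (!is.numeric(bin_width) || bin_width <= 0) stop("bin_width must be positive")
  lo <- bin_width * floor(min(diameters) / bin_width)
  hi <- bin_width * ceiling(max(diameters) / bin_width)
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- hist(diameters, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  out <- list(n = length(diameters), mean = mean(diameters),
              breaks = h$breaks, counts = h$counts, mids = h$mids,
              modal_bin_center = h$mids[which.max(h$counts)])
  class(out) <- "size_summary"
  out
}

#' @export
print.size_summary <- function(x, ...) {
  cat("Particle size summary: n =", x$n,
      sprintf("| mean = %.3g nm | modal bin = %.3g nm\n",
              x$mean, x$modal_bin_center))
  invisible(x)
}
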