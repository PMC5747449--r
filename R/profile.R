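#' Calibrated grey-scale image slice
#'
#' Container for a single 2-D MR-like slice: a matrix of grey values plus
#' the isotropic pixel spacing (mm/pixel) and the display window (level WL,
#' width WW) used to normalise intensities across imaging studies.
#'
#' @param pixels numeric matrix of grey values (rows = y, columns = x).
#' @param pixel_spacing pixel spacing in mm/pixel, > 0.
#' @param wl window level (grey value).
#' @param ww window width (grey value), > 0.
#' @return Object of class \code{"image_slice"}.
#' @export
image_slice <- function(pixels, pixel_spacing, wl = 420, ww = 821) {
  if (!is.matrix(pixels)) stop("pixels must be a matrix")
  if (!is.numeric(pixel_spacing) || pixel_spacing <= 0)
    stop("pixel_spacing must be positive")
  if (!is.numeric(ww) || ww <= 0) stop("window width must be positive")
  structure(list(pixels = pixels, pixel_spacing = pixel_spacing,
                 wl = wl, ww = ww),
            class = "image_slice")
}

#' @export
print.image_slice <- function(x, ...) {
  cat(sprintf("image_slice: %d x %d px @ %.4g mm/px, window %g/%g\n",
              nrow(x$pixels), ncol(x$pixels), x$pixel_spacing, x$wl, x$ww))
  invisible(x)
}

#' Apply the display window to a slice
#'
#' Linear window mapping \code{clip((raw - (WL - WW/2)) / WW, 0, 1)}: grey
#' values at \code{WL - WW/2} and below map to 0, at \code{WL + WW/2} and
#' above to 1, and the window level maps to (almost exactly) 0.5. Monotone
#' non-decreasing in the raw value. The returned slice carries the
#' normalised window \code{WL = 0.5, WW = 1}, under which windowing is
#' idempotent.
#'
#' @param slice an \code{\link{image_slice}}.
#' @return An \code{image_slice} with intensities in `[0, 1]`.
#' @export
apply_window <- function(slice) {
  stopifnot(inherits(slice, "image_slice"))
  if (slice$ww <= 0) stop("window width must be positive")
  lo <- slice$wl - slice$ww / 2
  px <- pmin(pmax((slice$pixels - lo) / slice$ww, 0), 1)
  dim(px) <- dim(slice$pixels)
  image_slice(px, slice$pixel_spacing, wl = 0.5, ww = 1)
}

#' Measurement line across a slice
#'
#' A straight line in pixel coordinates along which the intensity profile is
#' sampled. By convention the line starts at the subchondral-bone end, so
#' profile distance 0 is the bone end.
#'
#' @param start,end numeric (x, y) pixel coordinates (1-based, matrix column
#'   = x, row = y).
#' @param sampling_step sampling interval along the line in mm, > 0.
#' @param width_px averaging width of the line in pixels (default 1): the
#'   profile is averaged over this many parallel lines offset
#'   perpendicularly at one-pixel spacing, as in the line-width option of
#'   interactive profile tools.
#' @return Object of class \code{"measurement_line"}.
#' @export
measurement_line <- function(start, end, sampling_step, width_px = 1) {
  if (length(start) != 2L || length(end) != 2L) stop("start/end must be (x, y)")
  if (all(start == end)) stop("start and end must differ")
  if (!is.numeric(sampling_step) || sampling_step <= 0)
    stop("sampling_step must be positive")
  if (!is.numeric(width_px) || width_px < 1)
    stop("width_px must be >= 1")
  structure(list(start = as.numeric(start), end = as.numeric(end),
                 sampling_step = sampling_step,
                 width_px = as.integer(round(width_px))),
            class = "measurement_line")
}

# bilinear interpolation at continuous pixel coordinates (x = col, y = row)
.bilinear <- function(px, x, y) {
  x0 <- floor(x); y0 <- floor(y)
  x0 <- pmin(pmax(x0, 1), ncol(px) - 1L)
  y0 <- pmin(pmax(y0, 1), nrow(px) - 1L)
  fx <- x - x0; fy <- y - y0
  v00 <- px[cbind(y0, x0)]
  v01 <- px[cbind(y0, x0 + 1L)]
  v10 <- px[cbind(y0 + 1L, x0)]
  v11 <- px[cbind(y0 + 1L, x0 + 1L)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Extract an intensity profile along a measurement line
#'
#' Samples the (typically windowed) slice at regular intervals along the
#' line by bilinear interpolation. Distance 0 is at the line start (the bone
#' end by convention).
#'
#' @param slice an \code{\link{image_slice}}.
#' @param line a \code{\link{measurement_line}} with endpoints inside the
#'   image.
#' @return Object of class \code{"intensity_profile"}: a list with
#'   \code{distance} (mm, strictly increasing) and \code{intensity}.
#' @export
extract_profile <- function(slice, line) {
  stopifnot(inherits(slice, "image_slice"),
            inherits(line, "measurement_line"))
  px <- slice$pixels
  for (p in list(line$start, line$end)) {
    if (p[1] < 1 || p[1] > ncol(px) || p[2] < 1 || p[2] > nrow(px))
      stop("measurement line exits image bounds")
  }
  dvec <- line$end - line$start
  len_mm <- sqrt(sum(dvec^2)) * slice$pixel_spacing
  dist <- seq(0, len_mm, by = line$sampling_step)
  frac <- dist / len_mm
  xs <- line$start[1] + frac * dvec[1]
  ys <- line$start[2] + frac * dvec[2]
  w <- if (is.null(line$width_px)) 1L else line$width_px
  perp <- c(-dvec[2], dvec[1]) / sqrt(sum(dvec^2))
  offs <- seq(-(w - 1) / 2, (w - 1) / 2, length.out = w)
  vals <- 0
  for (o in offs) {
    xo <- xs + o * perp[1]
    yo <- ys + o * perp[2]
    if (any(xo < 1 | xo > ncol(px) | yo < 1 | yo > nrow(px)))
      stop("measurement line (including its width) exits image bounds")
    vals <- vals + .bilinear(px, xo, yo)
  }
  intensity_profile(dist, vals / w)
}

#' Construct an intensity profile
#'
#' @param distance strictly increasing distances from the line start (mm).
#' @param intensity grey values at those distances.
#' @return Object of class \code{"intensity_profile"}.
#' @export
intensity_profile <- function(distance, intensity) {
  if (length(distance) != length(intensity))
    stop("distance/intensity length mismatch")
  if (any(diff(distance) <= 0)) stop("distances must be strictly increasing")
  structure(list(distance = as.numeric(distance),
                 intensity = as.numeric(intensity)),
            class = "intensity_profile")
}

#' @export
print.intensity_profile <- function(x, ...) {
  cat(sprintf("intensity_profile: %d samples over %.4g mm\n",
              length(x$distance), max(x$distance) - min(x$distance)))
  invisible(x)
}

# centred moving average; edges use the partial window
.smooth_ma <- function(v, width) {
  if (width <= 1L) return(v)
  half <- (width - 1L) %/% 2L
  n <- length(v)
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(v[lo:hi])
  }, numeric(1))
}

#' Locate the cartilage-surface intensity peak on a profile
#'
#' Operationalises "the peak intensity point just prior to the profile
#' dropping off at the cartilage-joint cavity interface": scanning from the
#' bone end (distance 0) toward the joint end, the peak is the last sample
#' whose (smoothed) value attains the running maximum before the profile
#' falls below \code{drop_fraction} of that running maximum for at least
#' \code{min_run} consecutive samples.
#'
#' The drop is assessed relative to the profile baseline (global minimum of
#' the smoothed profile), which keeps the rule invariant under affine
#' intensity rescaling, and a candidate running maximum only qualifies once
#' its prominence above the baseline reaches \code{min_prominence} of the
#' profile's full dynamic range; this prevents noise fluctuations in the
#' dark subchondral-bone region from registering as a spurious cliff.
#'
#' @param profile an \code{\link{intensity_profile}} with >= 8 samples.
#' @param drop_fraction fraction of the running maximum (above baseline)
#'   below which samples count toward the sustained drop (default 0.5).
#' @param min_run number of consecutive sub-threshold samples that qualify
#'   as the drop-off (default 3).
#' @param smooth_width moving-average window (samples) applied before
#'   detection (default 3; 1 disables smoothing). The peak value is reported
#'   from the smoothed profile.
#' @param min_prominence fraction of the profile's dynamic range the running
#'   maximum must reach before a drop-off can qualify (default 0.5).
#' @return List of class \code{"profile_peak"}: \code{peak_distance} (mm),
#'   \code{peak_value}, \code{peak_index}, and the \code{smoothed} values
#'   used for detection.
#' @export
find_peak <- function(profile, drop_fraction = 0.5, min_run = 3,
                      smooth_width = 3, min_prominence = 0.5) {
  stopifnot(inherits(profile, "intensity_profile"))
  n <- length(profile$distance)
  if (n < 8L) stop("need at least 8 samples for peak analysis")
  v <- .smooth_ma(profile$intensity, smooth_width)
  if (diff(range(v)) == 0) stop("flat profile: no peak")
  base <- min(v)
  span <- max(v) - base
  runmax <- -Inf
  peak_idx <- NA_integer_
  below <- 0L
  for (i in seq_len(n)) {
    if (v[i] >= runmax) {
      runmax <- v[i]
      peak_idx <- i
    }
    if (runmax - base >= min_prominence * span &&
        v[i] - base < drop_fraction * (runmax - base)) {
      below <- below + 1L
      if (below >= min_run) {
        out <- list(peak_distance = profile$distance[peak_idx],
                    peak_value = v[peak_idx], peak_index = peak_idx,
                    smoothed = v)
        class(out) <- "profile_peak"
        return(out)
      }
    } else {
      below <- 0L
    }
  }
  stop("no cartilage-cavity interface detected (no qualifying drop-off)")
}

#' Half-peak point and peak-to-half-peak distance
#'
#' From the detected peak, scans toward the bone end (distance 0) for the
#' first crossing of the half level and locates it by linear interpolation
#' between the bracketing samples. By default the half level is relative to
#' the profile baseline on the bone side of the peak (the minimum smoothed
#' value between the bone end and the peak), which makes the distance
#' invariant under affine intensity rescaling; set
#' \code{baseline_offset = FALSE} for raw half-of-peak. A plateau lying
#' exactly at the half level is resolved toward the peak (the first
#' bracketing sample from the peak side is used).
#'
#' @param profile the \code{\link{intensity_profile}} the peak was found on.
#' @param peak a \code{"profile_peak"} from \code{\link{find_peak}}.
#' @param baseline_offset subtract the bone-side minimum before halving
#'   (default TRUE).
#' @return Object of class \code{"half_peak_result"}: \code{peak_distance},
#'   \code{peak_value}, \code{half_peak_distance_point} (mm),
#'   \code{half_level}, \code{peak_to_half_peak} (mm), \code{baseline}.
#' @export
half_peak <- function(profile, peak, baseline_offset = TRUE) {
  stopifnot(inherits(profile, "intensity_profile"),
            inherits(peak, "profile_peak"))
  v <- peak$smoothed
  d <- profile$distance
  pi_ <- peak$peak_index
  if (pi_ < 2L) stop("profile not defined on bone side of peak")
  baseline <- if (baseline_offset) min(v[seq_len(pi_)]) else 0
  level <- baseline + (peak$peak_value - baseline) / 2
  # first j below the peak with v[j] <= level; since the scan is from the
  # peak side, v[j + 1] > level there, so a plateau at the level resolves to
  # its peak-side edge
  cross <- NA_real_
  for (j in seq(pi_ - 1L, 1L)) {
    if (v[j] <= level) {
      cross <- if (v[j] == level) d[j] else
        d[j] + (level - v[j]) / (v[j + 1L] - v[j]) * (d[j + 1L] - d[j])
      break
    }
  }
  if (is.na(cross))
    stop("half-peak not reached on the bone side of the peak")
  out <- list(peak_distance = peak$peak_distance,
              peak_value = peak$peak_value,
              half_peak_distance_point = cross,
              half_level = level,
              peak_to_half_peak = peak$peak_distance - cross,
              baseline = baseline)
  class(out) <- "half_peak_result"
  out
}

#' @export
print.half_peak_result <- function(x, ...) {
  cat(sprintf(
    "half_peak: peak %.4g @ %.4g mm; half-level %.4g @ %.4g mm; width %.4g mm\n",
    x$peak_value, x$peak_distance, x$half_level,
    x$half_peak_distance_point, x$peak_to_half_peak))
  invisible(x)
}

#' Peak-to-half-peak distance of a profile (one-call wrapper)
#'
#' Runs \code{\link{find_peak}} then \code{\link{half_peak}}.
#'
#' @inheritParams find_peak
#' @inheritParams half_peak
#' @return A \code{"half_peak_result"}.
#' @export
measure_half_peak <- function(profile, drop_fraction = 0.5, min_run = 3,
                              smooth_width = 3, baseline_offset = TRUE) {
  pk <- find_peak(profile, drop_fraction = drop_fraction, min_run = min_run,
                  smooth_width = smooth_width)
  half_peak(profile, pk, baseline_offset = baseline_offset)
}

#' Post-injection distance as a percentage of the pre-injection value
#'
#' @param pre_mm pre-injection peak-to-half-peak distance (mm), > 0.
#' @param post_mm post-injection distance (mm).
#' @return \code{100 * post_mm / pre_mm}.
#' @export
percent_of_pre <- function(pre_mm, post_mm) {
  if (any(pre_mm <= 0)) stop("pre-injection distance must be positive")
  100 * post_mm / pre_mm
}
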