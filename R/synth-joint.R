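# run expr under a fixed RNG state, restoring the caller's state afterwards
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(eval.parent(substitute(expr)))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  eval.parent(substitute(expr))
}

#' Specification of a synthetic joint slice phantom
#'
#' Parameters of the 1-D cartilage intensity model used to render synthetic
#' pre/post-injection sagittal slices. The profile runs from the subchondral
#' bone (a signal void), rises across the cartilage to a bright peak at the
#' cartilage surface, and drops into the joint fluid; after nanoparticle
#' injection the fluid turns hypointense and the superficial
#' \code{permeation_depth} of cartilage is darkened by particle permeation
#' (modelled as the rise truncated at that depth). The ground-truth
#' peak-to-half-peak distance is available in closed form for both rise
#' shapes.
#'
#' @param cartilage_thickness cartilage thickness (mm), > 0.
#' @param bone_level grey value of the subchondral bone; the default
#'   \code{NULL} places it at the display-window floor \code{wl - ww / 2}
#'   (the bone plate renders as a signal void, so the windowed baseline is
#'   exactly zero).
#' @param cartilage_peak_value grey value at the cartilage surface.
#' @param rise_shape \code{"linear"} or \code{"gaussian-limb"}.
#' @param rise_sigma scale (mm) of the gaussian-limb rise (ignored for
#'   linear; default one third of the thickness).
#' @param joint_fluid_value_pre,joint_fluid_value_post grey value of the
#'   joint fluid before/after injection (post is hypointense).
#' @param permeation_depth darkened superficial cartilage depth after
#'   injection (mm), in `[0, cartilage_thickness]`.
#' @param noise_sd additive Gaussian noise SD (grey values).
#' @param pixel_spacing mm per pixel, > 0.
#' @param bone_margin,fluid_margin extent of the bone / fluid regions (mm).
#' @param n_rows image rows (the profile is extruded across rows).
#' @param wl,ww display window carried on the slices.
#' @param seed integer seed, or \code{NULL} to use the current RNG state.
#' @return A list of class \code{"joint_phantom_spec"}.
#' @export
joint_phantom_spec <- function(cartilage_thickness = 2,
                               bone_level = NULL,
                               cartilage_peak_value = 780,
                               rise_shape = c("linear", "gaussian-limb"),
                               rise_sigma = cartilage_thickness / 3,
                               joint_fluid_value_pre = 250,
                               joint_fluid_value_post = 30,
                               permeation_depth = 0,
                               noise_sd = 0,
                               pixel_spacing = 0.02,
                               bone_margin = 0.75,
                               fluid_margin = 1.25,
                               n_rows = 20,
                               wl = 420, ww = 821,
                               seed = NULL) {
  rise_shape <- match.arg(rise_shape)
  if (is.null(bone_level)) bone_level <- wl - ww / 2
  if (cartilage_thickness <= 0) stop("cartilage_thickness must be positive")
  if (permeation_depth < 0 || permeation_depth > cartilage_thickness)
    stop("permeation_depth must lie in [0, cartilage_thickness]")
  if (pixel_spacing <= 0) stop("pixel_spacing must be positive")
  if (noise_sd < 0) stop("noise_sd must be non-negative")
  structure(as.list(environment()), class = "joint_phantom_spec")
}

# closed-form ground-truth peak-to-half-peak distance (baseline-offset
# convention) for a rise truncated at depth d below the cartilage surface
.truth_distance <- function(spec, d) {
  t_ <- spec$cartilage_thickness
  if (spec$rise_shape == "linear") {
    (t_ - d) / 2
  } else {
    c2 <- 2 * spec$rise_sigma^2 * log(2)
    sqrt(d^2 + c2) - d
  }
}

#' Permeation depth producing a target post/pre distance ratio
#'
#' Inverts the phantom's closed-form geometry: returns the
#' \code{permeation_depth} (mm) for which the post-injection peak-to-half-peak
#' distance equals \code{ratio} times the pre-injection one.
#'
#' @param spec a \code{\link{joint_phantom_spec}}.
#' @param ratio target post/pre ratio in (0, 1].
#' @return Permeation depth in mm.
#' @export
permeation_for_ratio <- function(spec, ratio) {
  stopifnot(inherits(spec, "joint_phantom_spec"))
  if (ratio <= 0 || ratio > 1) stop("ratio must lie in (0, 1]")
  if (spec$rise_shape == "linear") {
    spec$cartilage_thickness * (1 - ratio)
  } else {
    cc <- spec$rise_sigma * sqrt(2 * log(2))
    cc * (1 - ratio^2) / (2 * ratio)
  }
}

# raw-grey profile value at distance x (mm from image left edge)
.joint_profile_value <- function(spec, x, fluid_value, d) {
  b0 <- spec$bone_margin
  t_ <- spec$cartilage_thickness
  surf <- b0 + t_ - d                 # effective cartilage surface
  amp <- spec$cartilage_peak_value - spec$bone_level
  v <- numeric(length(x))
  eps <- 1e-9
  v[x < b0 - eps] <- spec$bone_level
  # the surface sample itself carries the cartilage value; fluid strictly
  # beyond it, so the rendered peak matches the closed-form geometry
  idx <- x >= b0 - eps & x <= surf + eps
  if (spec$rise_shape == "linear") {
    v[idx] <- spec$bone_level + amp * (x[idx] - b0) / t_
  } else {
    s <- spec$rise_sigma
    v[idx] <- spec$bone_level + amp * exp(-((b0 + t_ - x[idx])^2) / (2 * s^2))
  }
  v[x > surf + eps] <- fluid_value
  v
}

#' Generate a pre/post-injection joint slice pair with ground truth
#'
#' Renders the 1-D cartilage profile model as a pair of calibrated 2-D
#' slices (profile along image columns, extruded across rows) and attaches
#' the closed-form ground-truth barrier statistics. With
#' \code{conditioned = TRUE} the spec's \code{permeation_depth} is applied to
#' the post-injection slice; with \code{FALSE} no permeation is applied.
#'
#' @param spec a \code{\link{joint_phantom_spec}}.
#' @param conditioned apply the spec's permeation depth (default TRUE).
#' @return List with \code{pre}, \code{post} (\code{\link{image_slice}}s
#'   sharing pixel spacing), \code{line} (the default
#'   \code{\link{measurement_line}}, bone end first) and \code{truth}
#'   (\code{pre_mm}, \code{post_mm}, \code{ratio}, \code{percent_of_pre},
#'   \code{permeation_depth}).
#' @export
generate_joint_phantom <- function(spec, conditioned = TRUE) {
  stopifnot(inherits(spec, "joint_phantom_spec"))
  d <- if (conditioned) spec$permeation_depth else 0
  width_mm <- spec$bone_margin + spec$cartilage_thickness + spec$fluid_margin
  n_col <- ceiling(width_mm / spec$pixel_spacing) + 1L
  x_mm <- (seq_len(n_col) - 1) * spec$pixel_spacing
  render <- function(fluid_value, depth) {
    row_v <- .joint_profile_value(spec, x_mm, fluid_value, depth)
    px <- matrix(rep(row_v, each = spec$n_rows), nrow = spec$n_rows)
    if (spec$noise_sd > 0) {
      px <- px + matrix(rnorm(length(px), sd = spec$noise_sd), nrow(px))
      px <- pmin(pmax(px, 0), 65535)
      dim(px) <- c(spec$n_rows, n_col)
    }
    image_slice(px, spec$pixel_spacing, wl = spec$wl, ww = spec$ww)
  }
  res <- .with_seed(spec$seed, list(
    pre = render(spec$joint_fluid_value_pre, 0),
    post = render(spec$joint_fluid_value_post, d)))
  pre_mm <- .truth_distance(spec, 0)
  post_mm <- .truth_distance(spec, d)
  # half-pixel sampling along the rows; the line averages across 8 pixel
  # rows (the line-width convention of interactive profile tools), which
  # suppresses single-pixel noise without blurring along the profile axis
  line <- measurement_line(c(1, spec$n_rows / 2 + 0.5),
                           c(n_col, spec$n_rows / 2 + 0.5),
                           sampling_step = spec$pixel_spacing / 2,
                           width_px = 8)
  list(pre = res$pre, post = res$post, line = line,
       truth = list(pre_mm = pre_mm, post_mm = post_mm,
                    ratio = post_mm / pre_mm,
                    percent_of_pre = 100 * post_mm / pre_mm,
                    permeation_depth = d))
}

#' Generate a cohort of joints with a common ground-truth ratio
#'
#' Convenience wrapper producing \code{n} independent pre/post pairs whose
#' ground-truth post/pre distance ratio equals \code{target_ratio}, and the
#' measured barrier statistics for each.
#'
#' @param n number of joints.
#' @param target_ratio ground-truth post/pre ratio in (0, 1].
#' @param spec base \code{\link{joint_phantom_spec}} (its
#'   \code{permeation_depth} and \code{seed} are overridden).
#' @param seed integer seed for the cohort.
#' @param ... passed to \code{\link{measure_barrier}}.
#' @return data.frame with one row per joint: measured \code{pre_mm},
#'   \code{post_mm}, \code{diff_mm}, \code{percent_of_pre}, plus the shared
#'   \code{truth_percent}.
#' @export
generate_joint_cohort <- function(n, target_ratio, spec = joint_phantom_spec(),
                                  seed = 1, ...) {
  stopifnot(n >= 1)
  spec$permeation_depth <- permeation_for_ratio(spec, target_ratio)
  rows <- .with_seed(seed, {
    seeds <- sample.int(.Machine$integer.max, n)
    lapply(seq_len(n), function(i) {
      sp <- spec
      sp$seed <- seeds[i]
      ph <- generate_joint_phantom(sp, conditioned = TRUE)
      m <- measure_barrier(ph$pre, ph$post, ph$line, ...)
      data.frame(pre_mm = m$pre_mm, post_mm = m$post_mm,
                 diff_mm = m$diff_mm, percent_of_pre = m$percent_of_pre)
    })
  })
  out <- do.call(rbind, rows)
  out$truth_percent <- 100 * target_ratio
  out
}

#' Generate an agarose-well concentration-series phantom
#'
#' One slice per concentration: a circular well (the nanoparticle solution)
#' centred in a uniform surround (the agarose gel), with optional additive
#' Gaussian noise. The well grey value is \code{response(concentration)}.
#'
#' @param concentrations ascending concentrations (ug/mL), non-empty.
#' @param response function mapping concentration to well grey value
#'   (monotone non-increasing for a hypointensity series).
#' @param control_value grey value of the agarose surround.
#' @param noise_sd additive Gaussian noise SD (grey values).
#' @param well_diameter_mm well diameter (default 6 mm).
#' @param pixel_spacing mm per pixel.
#' @param image_mm image side length (mm).
#' @param wl,ww display window.
#' @param seed integer seed or NULL.
#' @return List of class \code{"phantom_series"}: \code{slices} (one
#'   \code{\link{image_slice}} per concentration), \code{concentrations},
#'   \code{well_center} (pixel coords), \code{well_radius_mm},
#'   \code{control_value}.
#' @export
generate_phantom_series <- function(concentrations, response, control_value,
                                    noise_sd = 0, well_diameter_mm = 6,
                                    pixel_spacing = 0.2, image_mm = 12,
                                    wl = 420, ww = 821, seed = NULL) {
  if (length(concentrations) == 0L) stop("empty concentration list")
  if (any(diff(concentrations) <= 0))
    stop("concentrations must be sorted ascending")
  n_px <- ceiling(image_mm / pixel_spacing)
  ctr <- (n_px + 1) / 2
  r_px <- well_diameter_mm / 2 / pixel_spacing
  cols <- seq_len(n_px)
  inside <- outer((cols - ctr)^2, (cols - ctr)^2, "+") <= r_px^2
  slices <- .with_seed(seed, lapply(concentrations, function(conc) {
    px <- matrix(control_value, n_px, n_px)
    px[inside] <- response(conc)
    if (noise_sd > 0) {
      px <- px + matrix(rnorm(length(px), sd = noise_sd), n_px)
      px <- pmin(pmax(px, 0), 65535)
      dim(px) <- c(n_px, n_px)
    }
    image_slice(px, pixel_spacing, wl = wl, ww = ww)
  }))
  structure(list(slices = slices, concentrations = concentrations,
                 well_center = c(ctr, ctr),
                 well_radius_mm = well_diameter_mm / 2,
                 control_value = control_value),
            class = "phantom_series")
}

#' Threshold concentration from a phantom series
#'
#' Windows each slice, measures the well ROI and the agarose surround
#' (everything beyond 1.25 times the well radius), and applies
#' \code{\link{detect_threshold_concentration}}.
#'
#' @param series a \code{"phantom_series"}.
#' @param k hypointensity margin in control SDs (default 3).
#' @param min_control_sd floor for the control SD (normalised grey; guards
#'   the noise-free case where the surround SD is exactly 0).
#' @return The threshold concentration (ug/mL) or \code{NA_real_}.
#' @export
threshold_from_series <- function(series, k = 3, min_control_sd = 0.005) {
  stopifnot(inherits(series, "phantom_series"))
  r_roi <- series$well_radius_mm * 0.8   # stay clear of the rim
  stats_ <- lapply(series$slices, function(sl) {
    w <- apply_window(sl)
    roi <- roi_stats(w, series$well_center, r_roi)
    px <- w$pixels
    ctr <- series$well_center
    r_out <- series$well_radius_mm * 1.25 / sl$pixel_spacing
    cols <- seq_len(ncol(px)); rows <- seq_len(nrow(px))
    outside <- outer((rows - ctr[2])^2, (cols - ctr[1])^2, "+") > r_out^2
    list(well_mean = roi$mean, ctrl_mean = mean(px[outside]),
         ctrl_sd = sd(px[outside]))
  })
  ctrl_mean <- mean(vapply(stats_, `[[`, numeric(1), "ctrl_mean"))
  ctrl_sd <- max(mean(vapply(stats_, `[[`, numeric(1), "ctrl_sd")),
                 min_control_sd)
  detect_threshold_concentration(
    series$concentrations,
    vapply(stats_, `[[`, numeric(1), "well_mean"),
    ctrl_mean, ctrl_sd, k = k)
}
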