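#' Specification of a synthetic two-channel live/dead stack
#'
#' Spherical cells are placed uniformly at random (with a minimum
#' centre-to-centre separation across both channels) inside a 3-D volume:
#' live cells in the green channel, dead cells in the red channel. Spheres
#' are rendered with solid intensity and a one-voxel anti-aliased shell;
#' optional additive Gaussian noise.
#'
#' @param n_live,n_dead cell counts per channel.
#' @param live_diameter,dead_diameter cell diameters (um; defaults 8 and 6).
#' @param voxel_size length-3 voxel size (um per axis).
#' @param dims_um length-3 volume extent (um).
#' @param min_separation minimum centre separation (um); defaults to the
#'   larger diameter (non-overlapping regime).
#' @param amplitude sphere peak intensity (arbitrary units).
#' @param intensity_sd additive Gaussian noise SD.
#' @param margin_um keep-out margin from the volume faces (um).
#' @param seed integer seed or NULL.
#' @return List of class \code{"stack_spec"}.
#' @export
stack_spec <- function(n_live = 30, n_dead = 20,
                       live_diameter = 8, dead_diameter = 6,
                       voxel_size = c(2, 2, 2),
                       dims_um = c(200, 200, 60),
                       min_separation = max(live_diameter, dead_diameter),
                       amplitude = 1, intensity_sd = 0,
                       margin_um = max(live_diameter, dead_diameter),
                       seed = NULL) {
  if (live_diameter <= 0 || dead_diameter <= 0) stop("diameters must be positive")
  if (any(voxel_size <= 0)) stop("voxel sizes must be positive")
  if (intensity_sd < 0) stop("intensity_sd must be non-negative")
  structure(as.list(environment()), class = "stack_spec")
}

# place n centers uniformly with pairwise min separation; bounded retries
.place_centers <- function(n, dims, margin, min_sep, existing = NULL,
                           max_tries = 2000L) {
  centers <- existing
  placed <- matrix(numeric(0), ncol = 3)
  for (i in seq_len(n)) {
    ok <- FALSE
    for (try in seq_len(max_tries)) {
      p <- margin + runif(3) * (dims - 2 * margin)
      all_c <- rbind(centers, placed)
      if (is.null(all_c) || nrow(all_c) == 0L ||
          min(sqrt(rowSums(sweep(all_c, 2, p)^2))) >= min_sep) {
        placed <- rbind(placed, p)
        ok <- TRUE
        break
      }
    }
    if (!ok)
      stop("volume too small to place requested spheres at min_separation")
  }
  placed
}

# render spheres into a voxel array: solid core, 1-voxel anti-aliased shell
.render_spheres <- function(dim_vox, voxel_size, centers, radius_um,
                            amplitude) {
  arr <- array(0, dim_vox)
  if (is.null(centers) || nrow(centers) == 0L) return(arr)
  edge <- mean(voxel_size)            # shell width ~ one voxel
  for (s in seq_len(nrow(centers))) {
    ctr <- centers[s, ]
    lo <- pmax(1L, floor((ctr - radius_um - edge) / voxel_size) + 1L)
    hi <- pmin(dim_vox, ceiling((ctr + radius_um + edge) / voxel_size))
    ix <- lo[1]:hi[1]; iy <- lo[2]:hi[2]; iz <- lo[3]:hi[3]
    gx <- (ix - 0.5) * voxel_size[1] - ctr[1]
    gy <- (iy - 0.5) * voxel_size[2] - ctr[2]
    gz <- (iz - 0.5) * voxel_size[3] - ctr[3]
    d2 <- outer(outer(gx^2, gy^2, "+"), gz^2, "+")
    cov <- pmin(pmax((radius_um + edge / 2 - sqrt(d2)) / edge, 0), 1)
    arr[ix, iy, iz] <- pmax(arr[ix, iy, iz], amplitude * cov)
  }
  arr
}

#' Generate a two-channel fluorescence stack with ground truth
#'
#' @param spec a \code{\link{stack_spec}}.
#' @return Object of class \code{"fluor_stack"}: arrays \code{green} and
#'   \code{red} (x, y, z voxels), \code{voxel_size} (um), and \code{truth}
#'   (data.frame of true centres: \code{x_um, y_um, z_um, channel}).
#' @export
generate_stack <- function(spec) {
  stopifnot(inherits(spec, "stack_spec"))
  dim_vox <- ceiling(spec$dims_um / spec$voxel_size)
  .with_seed(spec$seed, {
    live_c <- .place_centers(spec$n_live, spec$dims_um, spec$margin_um,
                             spec$min_separation)
    dead_c <- .place_centers(spec$n_dead, spec$dims_um, spec$margin_um,
                             spec$min_separation, existing = live_c)
    green <- .render_spheres(dim_vox, spec$voxel_size, live_c,
                             spec$live_diameter / 2, spec$amplitude)
    red <- .render_spheres(dim_vox, spec$voxel_size, dead_c,
                           spec$dead_diameter / 2, spec$amplitude)
    if (spec$intensity_sd > 0) {
      green <- green + array(rnorm(length(green), sd = spec$intensity_sd),
                             dim_vox)
      red <- red + array(rnorm(length(red), sd = spec$intensity_sd), dim_vox)
      green[green < 0] <- 0
      red[red < 0] <- 0
    }
    mk <- function(m, ch) if (nrow(m) == 0L)
      data.frame(x_um = numeric(0), y_um = numeric(0), z_um = numeric(0),
                 channel = character(0))
    else data.frame(x_um = m[, 1], y_um = m[, 2], z_um = m[, 3],
                    channel = ch)
    structure(list(green = green, red = red, voxel_size = spec$voxel_size,
                   truth = rbind(mk(live_c, "green"), mk(dead_c, "red"))),
              class = "fluor_stack")
  })
}

#' @export
print.fluor_stack <- function(x, ...) {
  cat(sprintf("fluor_stack: %s voxels @ (%s) um, 2 channels\n",
              paste(dim(x$green), collapse = " x "),
              paste(x$voxel_size, collapse = ", ")))
  invisible(x)
}
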