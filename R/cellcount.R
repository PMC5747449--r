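# banded matrix applying a symmetric 1-D kernel along vectors of length n,
# with truncated-and-renormalised rows at the boundaries (keeps flats flat)
.conv_matrix <- function(n, kernel) {
  half <- (length(kernel) - 1L) %/% 2L
  k_mat <- matrix(0, n, n)
  for (i in seq_len(n)) {
    j <- (i - half):(i + half)
    keep <- j >= 1L & j <= n
    w <- kernel[keep]
    k_mat[i, j[keep]] <- w / sum(w)
  }
  k_mat
}

# second-difference matrix with edge replication
.d2_matrix <- function(n) {
  d2 <- matrix(0, n, n)
  for (i in 2:(n - 1L)) d2[i, (i - 1L):(i + 1L)] <- c(1, -2, 1)
  d2
}

# apply matrix A along dimension k of a 3-D array
.apply_along <- function(arr, a_mat, k) {
  perm <- c(k, setdiff(1:3, k))
  x <- aperm(arr, perm)
  d <- dim(x)
  y <- a_mat %*% matrix(x, nrow = d[1])
  dim(y) <- d
  aperm(y, order(perm))
}

.gauss_kernel <- function(sigma) {
  half <- max(1L, ceiling(3 * sigma))
  x <- (-half):half
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# scale-normalised Laplacian-of-Gaussian blob response (bright blobs ->
# positive response); sigma given per axis in voxels
.blob_response <- function(arr, sigma_vox) {
  sm <- arr
  for (k in 1:3)
    sm <- .apply_along(sm, .conv_matrix(dim(arr)[k], .gauss_kernel(sigma_vox[k])), k)
  resp <- array(0, dim(arr))
  for (k in 1:3)
    resp <- resp + sigma_vox[k]^2 * .apply_along(sm, .d2_matrix(dim(arr)[k]), k)
  -resp
}

# Otsu threshold on a numeric vector (256-bin histogram)
.otsu <- function(v, n_bins = 256L) {
  r <- range(v)
  if (diff(r) == 0) return(r[1])
  br <- seq(r[1], r[2], length.out = n_bins + 1L)
  h <- tabulate(findInterval(v, br, rightmost.closed = TRUE), n_bins)
  mids <- (br[-1] + br[-length(br)]) / 2
  w <- cumsum(h)
  mu <- cumsum(h * mids)
  tot_w <- w[n_bins]; tot_mu <- mu[n_bins]
  w1 <- w[-n_bins]; mu1 <- mu[-n_bins]
  w2 <- tot_w - w1
  valid <- w1 > 0 & w2 > 0
  between <- rep(-Inf, n_bins - 1L)
  between[valid] <- (tot_mu * w1[valid] / tot_w - mu1[valid])^2 /
    (w1[valid] / tot_w * (1 - w1[valid] / tot_w)) / tot_w
  mids[which.max(between)]
}

# strict local maxima over the 26-neighbourhood
.local_maxima <- function(resp) {
  d <- dim(resp)
  pad <- array(-Inf, d + 2L)
  pad[2:(d[1] + 1L), 2:(d[2] + 1L), 2:(d[3] + 1L)] <- resp
  is_max <- array(TRUE, d)
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    nb <- pad[(2:(d[1] + 1L)) + dx, (2:(d[2] + 1L)) + dy,
              (2:(d[3] + 1L)) + dz]
    is_max <- is_max & (resp >= nb) & !(resp == nb & (dx < 0 ||
      (dx == 0 && (dy < 0 || (dy == 0 && dz < 0)))))
  }
  which(is_max, arr.ind = TRUE)
}

#' Detection settings for 3-D sphere (cell) detection
#'
#' @param live_diameter,dead_diameter estimated cell diameters (um;
#'   defaults 8 for the green/live and 6 for the red/dead channel).
#' @param radius_scale multiplier on the estimated radius (default 1.0).
#' @param response_threshold absolute threshold on the blob response, or
#'   \code{NULL} for an Otsu threshold on the response histogram.
#' @param min_center_separation minimum centre separation as a fraction of
#'   the channel diameter (default 0.7); the weaker of two closer maxima is
#'   suppressed.
#' @return List of class \code{"detection_settings"}.
#' @export
detection_settings <- function(live_diameter = 8, dead_diameter = 6,
                               radius_scale = 1.0,
                               response_threshold = NULL,
                               min_center_separation = 0.7) {
  if (live_diameter <= 0 || dead_diameter <= 0)
    stop("diameters must be positive")
  if (radius_scale <= 0) stop("radius_scale must be positive")
  structure(as.list(environment()), class = "detection_settings")
}

#' Detect spherical cells in one channel of a 3-D stack
#'
#' Single-scale, scale-normalised Laplacian-of-Gaussian blob detection at
#' the scale implied by the channel's estimated diameter
#' (\code{sigma = radius_scale * diameter / 2 / sqrt(3)} per axis, converted
#' to voxels via the voxel size). Local maxima of the response above the
#' threshold are reported; maxima closer than
#' \code{min_center_separation * diameter} are suppressed keeping the
#' stronger response. Centres are reported in um (voxel-centre convention).
#'
#' @param stack a \code{"fluor_stack"} (see \code{\link{generate_stack}}) or
#'   a plain 3-D array (then \code{voxel_size} must be supplied).
#' @param channel \code{"green"} (live) or \code{"red"} (dead).
#' @param settings a \code{\link{detection_settings}}.
#' @param voxel_size voxel size override (um per axis).
#' @return data.frame with \code{x_um, y_um, z_um, response}, strongest
#'   first.
#' @export
detect_cells <- function(stack, channel = c("green", "red"),
                         settings = detection_settings(),
                         voxel_size = NULL) {
  channel <- match.arg(channel)
  if (inherits(stack, "fluor_stack")) {
    arr <- stack[[channel]]
    voxel_size <- stack$voxel_size
  } else {
    arr <- stack
    if (is.null(voxel_size)) stop("voxel_size required for a bare array")
  }
  if (length(dim(arr)) != 3L) stop("stack channel must be a 3-D array")
  diameter <- if (channel == "green") settings$live_diameter else
    settings$dead_diameter
  sigma_um <- settings$radius_scale * diameter / 2 / sqrt(3)
  sigma_vox <- sigma_um / voxel_size
  if (any(diameter / voxel_size < 2))
    stop("resolution too coarse: diameter under 2 voxels along an axis")
  empty <- data.frame(x_um = numeric(0), y_um = numeric(0),
                      z_um = numeric(0), response = numeric(0))
  if (max(arr) == min(arr)) return(empty)
  resp <- .blob_response(arr, sigma_vox)
  thr <- settings$response_threshold
  if (is.null(thr)) {
    pos_resp <- resp[resp > 0]
    if (length(pos_resp) == 0L) return(empty)
    thr <- .otsu(pos_resp)
  }
  peaks <- .local_maxima(resp)
  if (nrow(peaks) == 0L) return(empty)
  vals <- resp[peaks]
  keep <- vals > thr
  peaks <- peaks[keep, , drop = FALSE]
  vals <- vals[keep]
  if (nrow(peaks) == 0L) return(empty)
  o <- order(vals, decreasing = TRUE)
  peaks <- peaks[o, , drop = FALSE]
  vals <- vals[o]
  pos <- sweep(peaks - 0.5, 2, voxel_size, "*")
  min_sep <- settings$min_center_separation * diameter
  kept <- logical(nrow(pos))
  for (i in seq_len(nrow(pos))) {
    if (!any(kept)) { kept[i] <- TRUE; next }
    prev <- pos[kept, , drop = FALSE]
    kept[i] <- min(sqrt(rowSums(sweep(prev, 2, pos[i, ])^2))) >= min_sep
  }
  data.frame(x_um = pos[kept, 1], y_um = pos[kept, 2], z_um = pos[kept, 3],
             response = vals[kept])
}

#' Count live and dead cells in a two-channel stack
#'
#' Runs \code{\link{detect_cells}} independently on the green (live) and red
#' (dead) channels and assembles counts and the live fraction. Co-localised
#' green/red signal yields a centre in both counts.
#'
#' @param stack a \code{"fluor_stack"}.
#' @param settings a \code{\link{detection_settings}}.
#' @return Object of class \code{"cell_counts"}: \code{live_centers},
#'   \code{dead_centers}, \code{live_count}, \code{dead_count},
#'   \code{live_fraction} (percent), \code{edits} (audit trail, initially
#'   empty).
#' @export
count_cells <- function(stack, settings = detection_settings()) {
  live <- detect_cells(stack, "green", settings)
  dead <- detect_cells(stack, "red", settings)
  .cell_counts(live, dead)
}

.cell_counts <- function(live, dead, edits = list()) {
  n_l <- nrow(live); n_d <- nrow(dead)
  structure(list(live_centers = live, dead_centers = dead,
                 live_count = n_l, dead_count = n_d,
                 live_fraction = if (n_l + n_d > 0)
                   100 * n_l / (n_l + n_d) else NA_real_,
                 edits = edits),
            class = "cell_counts")
}

#' @export
print.cell_counts <- function(x, ...) {
  cat(sprintf("cell_counts: %d live / %d dead (%.1f%% live)",
              x$live_count, x$dead_count, x$live_fraction))
  if (length(x$edits)) cat(sprintf(" [%d manual edits]", length(x$edits)))
  cat("\n")
  invisible(x)
}

#' Apply manual review corrections to automated counts
#'
#' Adds or removes centres, mirroring the manual correction step after
#' automated selection. Removals must match an existing centre within
#' \code{tol_um}; removing a non-existent centre (including a duplicate
#' removal of the same centre) is an error. An audit trail of the applied
#' edits is kept on the result.
#'
#' @param result a \code{"cell_counts"}.
#' @param add_live,add_dead data.frames (or 3-column matrices) of centres
#'   (x_um, y_um, z_um) to add.
#' @param remove_live,remove_dead centres to remove.
#' @param tol_um matching tolerance for removals (default 1 um).
#' @return The corrected \code{"cell_counts"}.
#' @export
manual_review <- function(result, add_live = NULL, remove_live = NULL,
                          add_dead = NULL, remove_dead = NULL, tol_um = 1) {
  stopifnot(inherits(result, "cell_counts"))
  as_df <- function(x) {
    if (is.null(x)) return(NULL)
    x <- as.data.frame(x)
    names(x)[1:3] <- c("x_um", "y_um", "z_um")
    x
  }
  apply_edits <- function(centers, add, remove, what) {
    add <- as_df(add); remove <- as_df(remove)
    if (!is.null(remove)) for (i in seq_len(nrow(remove))) {
      if (nrow(centers) == 0L)
        stop("cannot remove ", what, " centre: none left")
      d <- sqrt((centers$x_um - remove$x_um[i])^2 +
                (centers$y_um - remove$y_um[i])^2 +
                (centers$z_um - remove$z_um[i])^2)
      j <- which.min(d)
      if (d[j] > tol_um)
        stop("cannot remove ", what, " centre: no match within ", tol_um,
             " um")
      centers <- centers[-j, , drop = FALSE]
    }
    if (!is.null(add)) {
      add$response <- NA_real_
      centers <- rbind(centers[c("x_um", "y_um", "z_um", "response")],
                       add[c("x_um", "y_um", "z_um", "response")])
    }
    centers
  }
  live <- apply_edits(result$live_centers, add_live, remove_live, "live")
  dead <- apply_edits(result$dead_centers, add_dead, remove_dead, "dead")
  edit <- list(add_live = as_df(add_live), remove_live = as_df(remove_live),
               add_dead = as_df(add_dead), remove_dead = as_df(remove_dead))
  if (all(vapply(edit, is.null, logical(1)))) return(result)
  .cell_counts(live, dead, edits = c(result$edits, list(edit)))
}

#' Viability percentage from live/dead counts
#'
#' @param live_count,dead_count non-negative counts; their sum must be
#'   positive.
#' @return Percent live: \code{100 * live / (live + dead)}.
#' @export
viability <- function(live_count, dead_count) {
  if (any(live_count < 0) || any(dead_count < 0)) stop("counts must be >= 0")
  if (any(live_count + dead_count == 0)) stop("no cells detected")
  100 * live_count / (live_count + dead_count)
}

#' Match detected centres to ground truth and score precision/recall
#'
#' Greedy nearest matching within \code{tol_um}: each truth centre may be
#' claimed by at most one detection.
#'
#' @param detected data.frame with x_um, y_um, z_um (e.g. from
#'   \code{\link{detect_cells}}).
#' @param truth data.frame of true centres with the same columns.
#' @param tol_um match tolerance in um.
#' @return List with \code{tp}, \code{fp}, \code{fn}, \code{precision},
#'   \code{recall}.
#' @export
match_detections <- function(detected, truth, tol_um) {
  n_det <- nrow(detected); n_tru <- nrow(truth)
  used <- logical(n_tru)
  tp <- 0L
  if (n_det > 0 && n_tru > 0) for (i in seq_len(n_det)) {
    d <- sqrt((truth$x_um - detected$x_um[i])^2 +
              (truth$y_um - detected$y_um[i])^2 +
              (truth$z_um - detected$z_um[i])^2)
    d[used] <- Inf
    j <- which.min(d)
    if (d[j] <= tol_um) { used[j] <- TRUE; tp <- tp + 1L }
  }
  list(tp = tp, fp = n_det - tp, fn = n_tru - tp,
       precision = if (n_det > 0) tp / n_det else NA_real_,
       recall = if (n_tru > 0) tp / n_tru else NA_real_)
}
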