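#' Measure the barrier statistic on a pre/post slice pair
#'
#' Applies the display window to both slices, extracts the intensity profile
#' along the same measurement line, and computes the peak-to-half-peak
#' distance before and after nanoparticle administration, the pre-post
#' difference, and the post distance as a percentage of the pre value.
#'
#' @param pre,post \code{\link{image_slice}} objects sharing pixel spacing.
#' @param line a \code{\link{measurement_line}} (bone end at the start).
#' @param ... passed to \code{\link{measure_half_peak}} (drop rule,
#'   smoothing, baseline handling).
#' @return List with \code{pre_mm}, \code{post_mm}, \code{diff_mm}
#'   (pre - post), \code{percent_of_pre}, and the two
#'   \code{"half_peak_result"} objects (\code{pre_result},
#'   \code{post_result}).
#' @export
measure_barrier <- function(pre, post, line, ...) {
  stopifnot(inherits(pre, "image_slice"), inherits(post, "image_slice"))
  if (abs(pre$pixel_spacing - post$pixel_spacing) > 1e-12)
    stop("pre and post slices must share pixel spacing")
  hp_pre <- measure_half_peak(extract_profile(apply_window(pre), line), ...)
  hp_post <- measure_half_peak(extract_profile(apply_window(post), line), ...)
  list(pre_mm = hp_pre$peak_to_half_peak,
       post_mm = hp_post$peak_to_half_peak,
       diff_mm = hp_pre$peak_to_half_peak - hp_post$peak_to_half_peak,
       percent_of_pre = percent_of_pre(hp_pre$peak_to_half_peak,
                                       hp_post$peak_to_half_peak),
       pre_result = hp_pre, post_result = hp_post)
}

#' Compare pre-post barrier differences between joint cohorts
#'
#' Takes per-joint pre- and post-injection peak-to-half-peak distances for
#' conditioned (matrix-depleted) and unconditioned joints, forms the
#' pre - post differences, and compares the cohorts with a tie-corrected
#' Kruskal-Wallis rank test and Dunn's pairwise comparison. Also reports the
#' per-cohort median and quartiles of the post distance as a percentage of
#' the pre value (lower percentages mean deeper nanoparticle permeation).
#'
#' @param conditioned,unconditioned data.frames with numeric columns
#'   \code{pre_mm} and \code{post_mm}, one row per joint (>= 2 rows each).
#' @return Object of class \code{"barrier_comparison"}: a per-joint table
#'   (\code{joints}), the Kruskal-Wallis/Dunn result (\code{test}), and
#'   per-group \code{percent_summary} (median, q1, q3 of percent-of-pre).
#' @export
compare_barrier_groups <- function(conditioned, unconditioned) {
  check <- function(d, nm) {
    if (!all(c("pre_mm", "post_mm") %in% names(d)))
      stop(nm, " needs columns pre_mm and post_mm")
    if (nrow(d) < 2L) stop(nm, " needs at least 2 joints")
    if (any(d$pre_mm <= 0)) stop("pre-injection distances must be positive")
    d
  }
  conditioned <- check(as.data.frame(conditioned), "conditioned")
  unconditioned <- check(as.data.frame(unconditioned), "unconditioned")
  joints <- rbind(
    data.frame(group = "conditioned", conditioned[c("pre_mm", "post_mm")]),
    data.frame(group = "unconditioned", unconditioned[c("pre_mm", "post_mm")]))
  joints$diff_mm <- joints$pre_mm - joints$post_mm
  joints$percent_of_pre <- percent_of_pre(joints$pre_mm, joints$post_mm)
  test <- kruskal_dunn(joints$diff_mm, joints$group)
  qs <- do.call(rbind, lapply(split(joints$percent_of_pre, joints$group),
                              function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(median = q[2], q1 = q[1], q3 = q[3])
  }))
  qs <- data.frame(group = rownames(qs), qs, row.names = NULL)
  out <- list(joints = joints, test = test, percent_summary = qs)
  class(out) <- "barrier_comparison"
  out
}

#' @export
print.barrier_comparison <- function(x, ...) {
  cat("Barrier comparison (pre - post peak-to-half-peak differences)\n")
  cat(sprintf("Kruskal-Wallis: H = %.4g, p = %.4g\n", x$test$H, x$test$p))
  cat("Percent-of-pre by group [median (q1; q3)]:\n")
  for (i in seq_len(nrow(x$percent_summary)))
    cat(sprintf("  %-14s %.2f%% (%.2f%%; %.2f%%)\n",
                x$percent_summary$group[i], x$percent_summary$median[i],
                x$percent_summary$q1[i], x$percent_summary$q3[i]))
  invisible(x)
}
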