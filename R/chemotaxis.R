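#' Average replicate fluorescence readings per sample
#'
#' Plate-reader wells are measured in replicate (typically triplicate); for
#' downstream analysis the readings are averaged per (group, sample).
#'
#' @param table data.frame with columns \code{group}, \code{sample} (donor /
#'   well id) and \code{fluorescence}; an optional \code{replicate} column is
#'   ignored for the average.
#' @return data.frame with columns \code{group}, \code{sample},
#'   \code{fluorescence} (the replicate mean), one row per (group, sample).
#' @export
average_replicates <- function(table) {
  need <- c("group", "sample", "fluorescence")
  if (!all(need %in% names(table)))
    stop("table must have columns: ", paste(need, collapse = ", "))
  if (any(!is.finite(table$fluorescence)))
    stop("non-finite fluorescence values")
  agg <- aggregate(fluorescence ~ group + sample, data = table, FUN = mean)
  agg[order(agg$group, agg$sample), , drop = FALSE]
}

#' Percent migration relative to the maximum-migration control
#'
#' @param sample_mean mean fluorescence of the sample well(s).
#' @param max_migration_mean mean fluorescence of the 100%-migration wells
#'   (bottom wells loaded directly with the dosing cell suspension); > 0.
#' @return Percentage \code{100 * sample_mean / max_migration_mean}.
#' @export
percent_migration <- function(sample_mean, max_migration_mean) {
  if (!is.numeric(max_migration_mean) || any(max_migration_mean <= 0))
    stop("max_migration_mean must be positive")
  100 * sample_mean / max_migration_mean
}

#' Holm-Sidak step-down adjustment
#'
#' Orders the m raw p-values ascending and sets
#' \code{adj_p[i] = max_{j <= i} (1 - (1 - p[j])^(m - j + 1))}, clipped to 1.
#' Monotone and never below the raw p.
#'
#' @param p numeric vector of raw p-values in `[0, 1]`.
#' @return Adjusted p-values in the original order.
#' @export
holm_sidak <- function(p) {
  if (any(!is.finite(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  m <- length(p)
  if (m == 0L) return(numeric(0))
  o <- order(p)
  adj <- numeric(m)
  running <- 0
  for (i in seq_len(m)) {
    v <- 1 - (1 - p[o[i]])^(m - i + 1)
    running <- max(running, v)
    adj[o[i]] <- min(running, 1)
  }
  adj
}

## shared internals ----------------------------------------------------------

# one-way fixed-effects decomposition from per-group (n, mean, sd);
# allow_constant governs the completely degenerate all-identical case
.oneway_from_moments <- function(n, m, s, allow_constant = FALSE) {
  k <- length(n)
  N <- sum(n)
  if (k < 2L) stop("need at least two groups")
  if (any(n < 2L)) stop("every group needs n >= 2")
  grand <- sum(n * m) / N
  ss_between <- sum(n * (m - grand)^2)
  ss_within <- sum((n - 1) * s^2)
  df_between <- k - 1
  df_within <- N - k
  if (ss_within <= 0 && ss_between > 0)
    stop("zero within-group variance: F undefined")
  if (ss_between == 0 && ss_within == 0) {
    if (!allow_constant) stop("zero variance everywhere: F undefined")
    # completely constant data: no evidence of a difference
    return(list(F = 0, df_between = df_between, df_within = df_within,
                p = 1, mse = 0, grand_mean = grand))
  }
  mse <- ss_within / df_within
  f <- (ss_between / df_between) / mse
  list(F = f, df_between = df_between, df_within = df_within,
       p = pf(f, df_between, df_within, lower.tail = FALSE),
       mse = mse, grand_mean = grand)
}

# treatment-vs-control pooled-MSE t contrasts + Holm-Sidak
.control_contrasts <- function(n, m, mse, df_within, control_idx) {
  idx <- setdiff(seq_along(n), control_idx)
  se <- sqrt(mse * (1 / n[idx] + 1 / n[control_idx]))
  tval <- (m[idx] - m[control_idx]) / se
  praw <- 2 * pt(-abs(tval), df_within)
  data.frame(comparison = idx, t = tval, p_raw = praw,
             p_adjusted = holm_sidak(praw))
}

.anova_result <- function(ow, groups, n, m, s, contrasts = NULL,
                          control = NULL) {
  out <- list(F = ow$F, df_between = ow$df_between, df_within = ow$df_within,
              p = ow$p, mse = ow$mse,
              groups = data.frame(group = groups, n = n, mean = m, sd = s,
                                  sem = s / sqrt(n)),
              control = control, comparisons = NULL)
  if (!is.null(contrasts)) {
    out$comparisons <- data.frame(group = groups[contrasts$comparison],
                                  t = contrasts$t, p_raw = contrasts$p_raw,
                                  p_adjusted = contrasts$p_adjusted)
  }
  class(out) <- "anova_result"
  out
}

#' @export
print.anova_result <- function(x, ...) {
  cat(sprintf("One-way ANOVA: F(%d, %d) = %.4g, p = %.4g\n",
              x$df_between, x$df_within, x$F, x$p))
  if (!is.null(x$comparisons)) {
    cat("Holm-Sidak contrasts vs control group", x$control, ":\n")
    print(format(x$comparisons, digits = 4), row.names = FALSE)
  }
  invisible(x)
}

#' One-way ANOVA with treatment-vs-control Holm-Sidak contrasts
#'
#' Fixed-effects one-way ANOVA on raw values followed by pooled-MSE t tests
#' of each treatment group against the designated control group, with
#' Holm-Sidak step-down adjustment over the treatment comparisons. The t
#' contrasts use the pooled within-group mean square on its full
#' \code{N - k} degrees of freedom (equal-variance form).
#'
#' @param values numeric vector of responses (e.g. per-sample mean
#'   fluorescence).
#' @param groups group labels, same length as \code{values}.
#' @param control label of the control group (default \code{"C"}).
#' @return An object of class \code{"anova_result"}: overall F, degrees of
#'   freedom, overall p, per-group summaries, and a \code{comparisons}
#'   data.frame with raw t, raw p and Holm-Sidak adjusted p per treatment
#'   group.
#' @export
anova_dunnett_style <- function(values, groups, control = "C") {
  groups <- as.character(groups)
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  if (!control %in% groups) stop("control group '", control, "' not present")
  lev <- unique(groups)
  n <- as.numeric(tapply(values, factor(groups, lev), length))
  m <- as.numeric(tapply(values, factor(groups, lev), mean))
  s <- as.numeric(tapply(values, factor(groups, lev), sd))
  ow <- .oneway_from_moments(n, m, s)
  ctr <- .control_contrasts(n, m, ow$mse, ow$df_within, match(control, lev))
  .anova_result(ow, lev, n, m, s, ctr, control)
}

#' One-way ANOVA reconstructed from printed summary statistics
#'
#' Reproduces a raw-data one-way ANOVA exactly from per-group (n, mean, SEM):
#' within-group sum of squares is \code{sum((n - 1) * (sem * sqrt(n))^2)},
#' between-group sum of squares comes from the group means and grand mean,
#' and the same pooled-MSE t / Holm-Sidak machinery as
#' \code{\link{anova_dunnett_style}} is applied downstream. The equivalence
#' with the raw-data ANOVA is an algebraic identity.
#'
#' @param summaries data.frame with columns \code{group}, \code{n},
#'   \code{mean}, \code{sem} (one row per group; n >= 2, sem >= 0).
#' @param control label of the control group, or \code{NULL} for the overall
#'   F test only.
#' @return An \code{"anova_result"} object (see
#'   \code{\link{anova_dunnett_style}}).
#' @examples
#' fig <- data.frame(group = c("C", "CW", "L", "M", "H"),
#'                   n = c(10, 5, 5, 5, 5),
#'                   mean = c(10076, 13390, 12517, 15666, 20108),
#'                   sem = c(1768, 2350, 2294, 2623, 2668))
#' anova_from_summary(fig, control = "C")
#' @export
anova_from_summary <- function(summaries, control = "C") {
  need <- c("group", "n", "mean", "sem")
  if (!all(need %in% names(summaries)))
    stop("summaries must have columns: ", paste(need, collapse = ", "))
  if (any(summaries$sem < 0)) stop("sem must be non-negative")
  if (any(summaries$n < 2)) stop("every group needs n >= 2")
  n <- summaries$n
  m <- summaries$mean
  s <- summaries$sem * sqrt(n)
  ow <- .oneway_from_moments(n, m, s)
  ctr <- NULL
  if (!is.null(control)) {
    if (!control %in% summaries$group)
      stop("control group '", control, "' not present")
    ctr <- .control_contrasts(n, m, ow$mse, ow$df_within,
                              match(control, summaries$group))
  }
  .anova_result(ow, as.character(summaries$group), n, m, s, ctr, control)
}

#' Overall one-way ANOVA of tissue weights across culture wells
#'
#' Plate-loading check: tests whether combined tissue weight differs between
#' experimental groups. Overall F only, no control-vs-treatment structure.
#'
#' @param weights numeric vector of per-well combined tissue weights.
#' @param groups group labels, same length as \code{weights}.
#' @return An \code{"anova_result"} object without contrasts.
#' @export
tissue_weight_anova <- function(weights, groups) {
  groups <- as.character(groups)
  if (length(weights) != length(groups)) stop("weights/groups length mismatch")
  lev <- unique(groups)
  n <- as.numeric(tapply(weights, factor(groups, lev), length))
  m <- as.numeric(tapply(weights, factor(groups, lev), mean))
  s <- as.numeric(tapply(weights, factor(groups, lev), sd))
  ow <- .oneway_from_moments(n, m, s, allow_constant = TRUE)
  .anova_result(ow, lev, n, m, s)
}
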