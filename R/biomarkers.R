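#' Replicate coefficient of variation
#'
#' \code{100 * sd / mean} across assay replicates (sample SD, n - 1
#' denominator). Scale-invariant: rescaling all replicates by a positive
#' constant leaves the CV unchanged.
#'
#' @param replicates numeric vector, length >= 2, with non-zero mean.
#' @return CV in percent.
#' @export
replicate_cv <- function(replicates) {
  if (length(replicates) < 2L) stop("need at least 2 replicates")
  m <- mean(replicates)
  if (m == 0) stop("replicate mean is zero: CV undefined")
  100 * sd(replicates) / m
}

.qc_decision <- function(accepted, reasons = character(0), value = NA_real_,
                         cv = NA_real_) {
  structure(list(accepted = accepted, reasons = reasons, value = value,
                 cv = cv),
            class = "qc_decision")
}

#' @export
print.qc_decision <- function(x, ...) {
  if (x$accepted) {
    cat(sprintf("QC: accepted, value = %.6g (CV %.3g%%)", x$value, x$cv))
    if (length(x$reasons)) cat(" [", paste(x$reasons, collapse = ", "), "]")
    cat("\n")
  } else {
    cat("QC: rejected (", paste(x$reasons, collapse = ", "), ")\n", sep = "")
  }
  invisible(x)
}

#' Multiplex immunoassay acceptance rule
#'
#' A measurement is reported only when it falls inside the assay's measurable
#' range, the associated quality control shows a recovery between the stated
#' bounds (endpoints inclusive), and the replicate CV is strictly below the
#' CV limit. The accepted value is the replicate mean multiplied by the
#' dilution factor.
#'
#' @param replicates numeric vector of replicate concentration readings
#'   (length >= 2).
#' @param dilution_factor dilution applied before assay (>= 1).
#' @param qc_recovery recovery (percent) of the associated quality control.
#' @param in_range logical; whether the reading lies inside the assay's
#'   measurable range.
#' @param range_side when \code{in_range} is \code{FALSE}, which side of the
#'   measurable range the reading fell on (\code{"below"} or \code{"above"});
#'   out-of-range values are censored, not zeroed.
#' @param cv_limit CV acceptance limit in percent (strict \code{<}; default 15).
#' @param recovery_range inclusive recovery bounds in percent
#'   (default \code{c(70, 130)}).
#' @return A \code{"qc_decision"}: \code{accepted}, \code{reasons} (subset of
#'   \code{cv_exceeded}, \code{recovery_out_of_range}, \code{below_range},
#'   \code{above_range}), \code{value} (dilution-corrected mean when
#'   accepted), \code{cv}.
#' @export
qc_multiplex <- function(replicates, dilution_factor = 1, qc_recovery = 100,
                         in_range = TRUE, range_side = c("below", "above"),
                         cv_limit = 15, recovery_range = c(70, 130)) {
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  cv <- replicate_cv(replicates)
  reasons <- character(0)
  if (!isTRUE(in_range))
    reasons <- c(reasons, paste0(match.arg(range_side), "_range"))
  if (qc_recovery < recovery_range[1] || qc_recovery > recovery_range[2])
    reasons <- c(reasons, "recovery_out_of_range")
  if (cv >= cv_limit) reasons <- c(reasons, "cv_exceeded")
  if (length(reasons))
    return(.qc_decision(FALSE, reasons, cv = cv))
  .qc_decision(TRUE, value = mean(replicates) * dilution_factor, cv = cv)
}

#' Competitive-ELISA replicate rule with leave-one-out outlier exclusion
#'
#' If the replicate CV exceeds the outlier limit (strict \code{>}), the
#' single replicate whose removal minimises the CV of the remainder is
#' dropped; if the CV still exceeds the limit the measurement is excluded.
#' Otherwise the dilution-corrected replicate mean is accepted. The
#' leave-one-out rule is deterministic and order-independent.
#'
#' @param replicates numeric vector, length >= 2 (>= 3 for removal to leave
#'   a computable CV).
#' @param dilution_factor dilution applied before assay (>= 1).
#' @param cv_outlier_limit CV limit in percent triggering exclusion
#'   (default 30).
#' @return A \code{"qc_decision"}; when a replicate was removed,
#'   \code{reasons} contains \code{outlier_removed} and the element
#'   \code{removed} gives its value.
#' @export
qc_pge2 <- function(replicates, dilution_factor = 1, cv_outlier_limit = 30) {
  if (length(replicates) < 2L) stop("need at least 2 replicates")
  if (dilution_factor < 1) stop("dilution_factor must be >= 1")
  cv <- replicate_cv(replicates)
  if (cv <= cv_outlier_limit)
    return(.qc_decision(TRUE, value = mean(replicates) * dilution_factor,
                        cv = cv))
  if (length(replicates) < 3L)
    return(.qc_decision(FALSE, "cv_exceeded", cv = cv))
  loo_cv <- vapply(seq_along(replicates),
                   function(i) replicate_cv(replicates[-i]), numeric(1))
  drop_idx <- which.min(loo_cv)
  if (loo_cv[drop_idx] > cv_outlier_limit)
    return(.qc_decision(FALSE, "cv_exceeded", cv = cv))
  kept <- replicates[-drop_idx]
  out <- .qc_decision(TRUE, "outlier_removed",
                      value = mean(kept) * dilution_factor,
                      cv = loo_cv[drop_idx])
  out$removed <- replicates[drop_idx]
  out
}

#' Kruskal-Wallis rank test with Dunn's post-hoc comparisons
#'
#' Tie-corrected Kruskal-Wallis H (via \code{\link[stats]{kruskal.test}})
#' followed by Dunn's z for pairwise comparisons on the pooled ranks:
#' \deqn{z = (\bar R_i - \bar R_j) /
#'   \sqrt{\left(\frac{N(N+1)}{12} - \frac{\sum (t^3 - t)}{12 (N-1)}\right)
#'   (1/n_i + 1/n_j)}}
#' with two-sided normal p-values, reported unadjusted and
#' Bonferroni-adjusted. When \code{control} is given only treatment-vs-control
#' comparisons are made; otherwise all pairs.
#'
#' @param values numeric response vector.
#' @param groups group labels, same length as \code{values}; every group
#'   needs >= 2 observations.
#' @param control optional control-group label restricting the comparisons.
#' @return Object of class \code{"kruskal_dunn"}: \code{H}, \code{df},
#'   \code{p}, mean ranks per group, and a \code{comparisons} data.frame
#'   (z, p_raw, p_bonferroni).
#' @export
kruskal_dunn <- function(values, groups, control = NULL) {
  groups <- as.character(groups)
  if (length(values) != length(groups)) stop("values/groups length mismatch")
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least 2 groups")
  n <- table(factor(groups, lev))
  if (any(n < 2L)) stop("every group needs >= 2 observations")
  if (length(unique(values)) == 1L)
    stop("all values identical across groups: ranks degenerate")
  kw <- kruskal.test(values, factor(groups, lev))
  N <- length(values)
  r <- rank(values)
  rbar <- tapply(r, factor(groups, lev), mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  var_base <- N * (N + 1) / 12 - tie_term
  if (is.null(control)) {
    pairs <- utils::combn(lev, 2, simplify = FALSE)
  } else {
    if (!control %in% lev) stop("control group '", control, "' not present")
    pairs <- lapply(setdiff(lev, control), function(g) c(g, control))
  }
  cmp <- do.call(rbind, lapply(pairs, function(p) {
    i <- p[1]; j <- p[2]
    z <- (rbar[[i]] - rbar[[j]]) /
      sqrt(var_base * (1 / n[[i]] + 1 / n[[j]]))
    data.frame(group1 = i, group2 = j, z = z,
               p_raw = 2 * pnorm(-abs(z)))
  }))
  cmp$p_bonferroni <- pmin(1, cmp$p_raw * nrow(cmp))
  out <- list(H = unname(kw$statistic), df = unname(kw$parameter),
              p = kw$p.value,
              mean_ranks = data.frame(group = lev, n = as.integer(n),
                                      mean_rank = as.numeric(rbar)),
              comparisons = cmp, control = control)
  class(out) <- "kruskal_dunn"
  out
}

#' @export
print.kruskal_dunn <- function(x, ...) {
  cat(sprintf("Kruskal-Wallis: H = %.4g, df = %d, p = %.4g\n",
              x$H, x$df, x$p))
  cat("Dunn comparisons", if (!is.null(x$control))
    paste0("(vs control ", x$control, ")"), ":\n")
  print(format(x$comparisons, digits = 4), row.names = FALSE)
  invisible(x)
}
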