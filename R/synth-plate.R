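#' Specification of a synthetic transwell plate
#'
#' Group-level targets for generating a long-format plate table: per-group
#' sample (donor) means, SEMs and sample sizes, the number of technical
#' replicates per well, and optionally a maximum-migration control group.
#' In exact-moments mode the generated per-group sample means and SEMs equal
#' the specification to machine precision (samples are drawn and then
#' affinely re-standardised to the target mean/SD), which makes the
#' summary-vs-raw ANOVA equivalence an exact test.
#'
#' @param group_means named numeric vector: mean fluorescence per group.
#' @param group_sems named numeric vector: SEM per group (>= 0).
#' @param group_ns named numeric vector: samples (donors) per group (>= 2).
#' @param n_replicates technical replicates per well (default 3).
#' @param replicate_sd SD of within-well replicate scatter (replicates are
#'   recentred so each well's replicate mean is exact).
#' @param max_migration_mean,max_migration_sem,max_migration_n optional
#'   100%-migration (MAX) group.
#' @param exact_moments re-standardise to exact moments (default TRUE).
#' @param seed integer seed or NULL.
#' @return List of class \code{"plate_spec"}.
#' @export
plate_spec <- function(group_means, group_sems, group_ns,
                       n_replicates = 3, replicate_sd = 0,
                       max_migration_mean = NULL,
                       max_migration_sem = 0, max_migration_n = 3,
                       exact_moments = TRUE, seed = NULL) {
  g <- names(group_means)
  if (is.null(g) || !identical(g, names(group_sems)) ||
      !identical(g, names(group_ns)))
    stop("group_means, group_sems, group_ns must share group names")
  if (any(group_sems < 0)) stop("SEMs must be non-negative")
  if (any(group_ns < 2)) stop("every group needs n >= 2")
  if (n_replicates < 1) stop("n_replicates must be >= 1")
  structure(list(group_means = group_means, group_sems = group_sems,
                 group_ns = group_ns, n_replicates = n_replicates,
                 replicate_sd = replicate_sd,
                 max_migration_mean = max_migration_mean,
                 max_migration_sem = max_migration_sem,
                 max_migration_n = max_migration_n,
                 exact_moments = exact_moments, seed = seed),
            class = "plate_spec")
}

# draw n values with exactly the requested mean and SD
.exact_moments_sample <- function(n, mean, sd) {
  if (sd == 0) return(rep(mean, n))
  z <- rnorm(n)
  while (sd(z) == 0) z <- rnorm(n)   # degenerate draw, essentially never
  mean + sd * (z - mean(z)) / sd(z)
}

#' Generate a long-format transwell plate table
#'
#' @param spec a \code{\link{plate_spec}}.
#' @return data.frame with columns \code{well}, \code{group}, \code{sample}
#'   (donor id), \code{replicate}, \code{fluorescence}. In exact-moments
#'   mode, averaging replicates per sample and summarising per group
#'   reproduces the spec's means and SEMs to machine precision.
#' @export
generate_plate <- function(spec) {
  stopifnot(inherits(spec, "plate_spec"))
  groups <- names(spec$group_means)
  means <- spec$group_means
  sems <- spec$group_sems
  ns <- spec$group_ns
  if (!is.null(spec$max_migration_mean)) {
    groups <- c(groups, "MAX")
    means <- c(means, MAX = unname(spec$max_migration_mean))
    sems <- c(sems, MAX = unname(spec$max_migration_sem))
    ns <- c(ns, MAX = unname(spec$max_migration_n))
  }
  .with_seed(spec$seed, {
    rows <- lapply(groups, function(g) {
      n <- ns[[g]]
      sd_g <- sems[[g]] * sqrt(n)
      donor_means <- if (spec$exact_moments)
        .exact_moments_sample(n, means[[g]], sd_g)
      else rnorm(n, means[[g]], sd_g)
      do.call(rbind, lapply(seq_len(n), function(i) {
        jitter <- if (spec$replicate_sd > 0 && spec$n_replicates > 1) {
          e <- rnorm(spec$n_replicates, sd = spec$replicate_sd)
          e - mean(e)                  # well replicate mean stays exact
        } else rep(0, spec$n_replicates)
        data.frame(well = sprintf("%s_%02d", g, i), group = g,
                   sample = sprintf("%s_%02d", g, i),
                   replicate = seq_len(spec$n_replicates),
                   fluorescence = donor_means[i] + jitter)
      }))
    })
    do.call(rbind, rows)
  })
}

#' Group summaries (n, mean, SEM) from a plate table
#'
#' Averages replicates per sample, then summarises per group — the
#' summarisation whose output \code{\link{anova_from_summary}} consumes.
#'
#' @param table a plate data.frame (see \code{\link{generate_plate}}).
#' @return data.frame with columns \code{group}, \code{n}, \code{mean},
#'   \code{sem}.
#' @export
summarize_plate <- function(table) {
  per_sample <- average_replicates(table)
  g <- unique(per_sample$group)
  do.call(rbind, lapply(g, function(gg) {
    v <- per_sample$fluorescence[per_sample$group == gg]
    data.frame(group = gg, n = length(v), mean = mean(v),
               sem = sd(v) / sqrt(length(v)))
  }))
}

#' Generate a filtration-loss calibration series
#'
#' Observed concentrations are the expected values reduced by a uniform
#' mass-loss fraction, with optional proportional Gaussian noise.
#'
#' @param expected expected concentrations (ug/mL), > 0.
#' @param loss_fraction uniform mass-loss fraction in `[0, 1)`.
#' @param noise_cv proportional noise CV (fraction of the observed value).
#' @param seed integer seed or NULL.
#' @return data.frame with columns \code{expected}, \code{observed}.
#' @export
generate_calibration_series <- function(expected = c(1000, 500, 250, 100,
                                                     50, 25, 5, 1),
                                        loss_fraction = 0.44,
                                        noise_cv = 0, seed = NULL) {
  if (any(expected <= 0)) stop("expected concentrations must be positive")
  if (loss_fraction < 0 || loss_fraction >= 1)
    stop("loss_fraction must lie in [0, 1)")
  .with_seed(seed, {
    obs <- expected * (1 - loss_fraction)
    if (noise_cv > 0) obs <- obs * (1 + rnorm(length(obs), sd = noise_cv))
    data.frame(expected = expected, observed = pmax(obs, 0))
  })
}

#' Generate a synthetic particle-diameter sample
#'
#' Log-normal diameters with the requested arithmetic mean and SD,
#' emulating a TEM sizing sample.
#'
#' @param n number of particles (default 172).
#' @param mean_nm target arithmetic mean diameter (nm).
#' @param sd_nm target SD (nm).
#' @param seed integer seed or NULL.
#' @return Numeric vector of diameters (nm).
#' @export
generate_diameters <- function(n = 172, mean_nm = 12, sd_nm = 3,
                               seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (mean_nm <= 0 || sd_nm <= 0) stop("mean and sd must be positive")
  s2 <- log(1 + (sd_nm / mean_nm)^2)
  .with_seed(seed, rlnorm(n, meanlog = log(mean_nm) - s2 / 2,
                          sdlog = sqrt(s2)))
}
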