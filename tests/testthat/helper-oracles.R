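# independent oracles and shared fixtures for the test suite

# printed neutrophil-assay group summaries (mean, SEM, n per group)
fig6_summaries <- function() {
  data.frame(group = c("C", "CW", "L", "M", "H"),
             n = c(10, 5, 5, 5, 5),
             mean = c(10076, 13390, 12517, 15666, 20108),
             sem = c(1768, 2350, 2294, 2623, 2668))
}

# mid-ranks by explicit enumeration (no call to rank())
oracle_ranks <- function(x) {
  vapply(x, function(v) sum(x < v) + (1 + sum(x == v)) / 2, numeric(1))
}

# tie-corrected Kruskal-Wallis H from first principles
oracle_kw_h <- function(values, groups) {
  r <- oracle_ranks(values)
  n_tot <- length(values)
  h <- 0
  for (g in unique(groups)) {
    rg <- r[groups == g]
    h <- h + length(rg) * (mean(rg) - (n_tot + 1) / 2)^2
  }
  h <- 12 * h / (n_tot * (n_tot + 1))
  ties <- table(values)
  h / (1 - sum(ties^3 - ties) / (n_tot^3 - n_tot))
}

# Dunn z for a pair of groups, from enumerated ranks
oracle_dunn_z <- function(values, groups, g1, g2) {
  r <- oracle_ranks(values)
  n_tot <- length(values)
  ties <- table(values)
  v <- n_tot * (n_tot + 1) / 12 - sum(ties^3 - ties) / (12 * (n_tot - 1))
  n1 <- sum(groups == g1)
  n2 <- sum(groups == g2)
  (mean(r[groups == g1]) - mean(r[groups == g2])) /
    sqrt(v * (1 / n1 + 1 / n2))
}

# half-peak crossing by dense piecewise-linear resampling of the smoothed
# profile, scanning from the peak toward distance 0
oracle_half_crossing <- function(distance, smoothed, peak_index, level,
                                 factor = 1000) {
  d_seg <- distance[seq_len(peak_index)]
  v_seg <- smoothed[seq_len(peak_index)]
  dense_d <- seq(min(d_seg), max(d_seg), length.out = factor * length(d_seg))
  dense_v <- approx(d_seg, v_seg, xout = dense_d)$y
  for (i in rev(seq_along(dense_d))) {
    if (dense_v[i] <= level) return(dense_d[i])
  }
  NA_real_
}

# exhaustive leave-k-out CV rule for the PGE2 exclusion decision: does any
# single removal bring the CV to <= limit, and which removal minimises it
oracle_pge2 <- function(replicates, limit = 30) {
  cv <- function(x) 100 * sd(x) / mean(x)
  if (cv(replicates) <= limit)
    return(list(accepted = TRUE, removed = NA_real_))
  subs <- lapply(seq_along(replicates), function(i) replicates[-i])
  cvs <- vapply(subs, cv, numeric(1))
  best <- which.min(cvs)
  if (cvs[best] <= limit)
    list(accepted = TRUE, removed = replicates[best])
  else list(accepted = FALSE, removed = NA_real_)
}

# merge detections from overlapping tiles: greedy strongest-first
# suppression at min_sep (same rule as the detector)
merge_detections <- function(det, min_sep) {
  det <- det[order(det$response, decreasing = TRUE), , drop = FALSE]
  kept <- logical(nrow(det))
  for (i in seq_len(nrow(det))) {
    if (!any(kept)) { kept[i] <- TRUE; next }
    prev <- det[kept, , drop = FALSE]
    d <- sqrt((prev$x_um - det$x_um[i])^2 + (prev$y_um - det$y_um[i])^2 +
              (prev$z_um - det$z_um[i])^2)
    kept[i] <- min(d) >= min_sep
  }
  det[kept, , drop = FALSE]
}
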