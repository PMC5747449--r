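test_that("display windowing maps the window linearly onto [0, 1]", {
  px <- matrix(c(9, 9.5, 420, 830.5, 2000, 100), 2, 3)
  sl <- image_slice(px, 0.05, wl = 420, ww = 821)
  w <- apply_window(sl)
  expect_equal(w$pixels[1, 2], 0.5, tolerance = 1 / 821)
  expect_equal(w$pixels[1, 1], 0)       # below the floor clips to 0
  expect_equal(w$pixels[2, 2], 1)       # at the ceiling clips to 1
  expect_true(all(diff(w$pixels[order(px)]) >= 0))
  # idempotent on already-normalized data
  expect_equal(apply_window(w)$pixels, w$pixels)
  expect_error(image_slice(px, 0.05, ww = 0), "positive")
})

test_that("profile extraction is exact bilinear sampling", {
  const <- image_slice(matrix(3.7, 10, 20), 0.1)
  line <- measurement_line(c(2, 5), c(18, 5), sampling_step = 0.1)
  p <- extract_profile(const, line)
  expect_true(all(p$intensity == 3.7))

  ramp <- image_slice(matrix(rep(seq_len(30), each = 12), nrow = 12), 0.1)
  lr <- measurement_line(c(1, 6), c(30, 6), sampling_step = 0.05)
  pr <- extract_profile(ramp, lr)
  # ramp of 1 grey per pixel = 10 grey per mm
  fit <- coef(lm(pr$intensity ~ pr$distance))
  expect_equal(unname(fit[2]), 10, tolerance = 1e-6)
  expect_lt(max(abs(pr$intensity - (1 + 10 * pr$distance))), 1e-6)

  # diagonal line: intensity gain per mm scales with the direction cosine
  ld <- measurement_line(c(1, 1), c(11, 11), sampling_step = 0.05)
  pd <- extract_profile(ramp, ld)
  fit_d <- coef(lm(pd$intensity ~ pd$distance))
  expect_equal(unname(fit_d[2]), 10 / sqrt(2), tolerance = 1e-6)

  out <- measurement_line(c(0, 5), c(18, 5), sampling_step = 0.1)
  expect_error(extract_profile(const, out), "bounds")
})

test_that("peak detection finds the last running maximum before the cliff", {
  d <- seq(0, 3, by = 0.05)
  tri <- intensity_profile(d, pmax(0.05, pmin(d / 2, 1 - 3.8 * (d - 2))))
  pk <- find_peak(tri, smooth_width = 1)
  expect_equal(pk$peak_distance, 2, tolerance = 0.05)
  expect_equal(pk$peak_value, 1, tolerance = 0.05)

  # two bumps before the cliff: the later, higher bump is the peak
  bump <- function(x, c0, h, w) h * exp(-((x - c0) / w)^2)
  v2 <- 0.36 + bump(d, 1, 0.24, 0.3) + bump(d, 2.5, 0.54, 0.25)
  v2[d > 2.7] <- 0.02
  two <- intensity_profile(d, v2)
  pk2 <- find_peak(two, smooth_width = 1)
  expect_equal(pk2$peak_distance, 2.5, tolerance = 0.1)
  # oracle: global max over samples before the cliff
  expect_equal(pk2$peak_index, which.max(v2))

  expect_error(find_peak(intensity_profile(d, d), smooth_width = 1),
               "no cartilage-cavity interface")
  expect_error(find_peak(intensity_profile(d, rep(1, length(d)))), "flat")
  expect_error(find_peak(intensity_profile(1:5, 1:5)), "8 samples")
})

test_that("half-peak localization matches closed-form geometry", {
  d <- seq(0, 3, by = 0.01)
  # symmetric triangle: apex 1 at 2 mm rising from 0 at 0 mm
  tri <- intensity_profile(d, pmax(0, pmin(d / 2, 1 - 6 * (d - 2))))
  hp <- measure_half_peak(tri, smooth_width = 1)
  expect_equal(hp$half_peak_distance_point, 1, tolerance = 0.011)
  expect_equal(hp$peak_to_half_peak, 1, tolerance = 0.015)

  # gaussian limb with scale sigma: width = sigma * sqrt(2 log 2)
  for (sig in c(0.2, 0.35, 0.5)) {
    g <- exp(-(pmax(2 - d, 0))^2 / (2 * sig^2))
    g[d > 2] <- 0.02
    hpg <- measure_half_peak(intensity_profile(d, g), smooth_width = 1)
    expect_equal(hpg$peak_to_half_peak, sig * sqrt(2 * log(2)),
                 tolerance = 0.015)
  }

  # plateau exactly at the half level: tie resolves toward the peak
  v <- c(rep(0, 20), seq(0, 0.5, length.out = 11), rep(0.5, 10),
         seq(0.5, 1, length.out = 11), 1, rep(0.02, 10))
  dd <- seq_along(v) * 0.05
  pk <- find_peak(intensity_profile(dd, v), smooth_width = 1)
  hp2 <- half_peak(intensity_profile(dd, v), pk)
  plateau_end <- dd[max(which(v == 0.5))]
  expect_equal(hp2$half_peak_distance_point, plateau_end, tolerance = 1e-9)

  # profile that never falls to half of peak on the bone side
  hi <- intensity_profile(d, pmin(0.9 + d / 30, 1 - 6 * pmax(d - 2, 0)))
  pkh <- find_peak(hi, smooth_width = 1)
  expect_error(half_peak(hi, pkh, baseline_offset = FALSE), "not reached")
})

test_that("peak-to-half-peak distance is affine-invariant in intensity", {
  set.seed(12)
  d <- seq(0, 3, by = 0.02)
  for (i in 1:20) {
    sig <- runif(1, 0.3, 0.7)
    v <- exp(-(pmax(2 - d, 0))^2 / (2 * sig^2))
    v[d > 2] <- 0.03
    base <- measure_half_peak(intensity_profile(d, v), smooth_width = 1)
    gain <- runif(1, 0.2, 5)
    offset <- runif(1, 0, 2)
    scaled <- measure_half_peak(intensity_profile(d, gain * v + offset),
                                smooth_width = 1)
    expect_equal(scaled$peak_to_half_peak, base$peak_to_half_peak,
                 tolerance = 1e-9)
  }
})

test_that("percent of pre-injection value is plain ratio arithmetic", {
  expect_equal(percent_of_pre(1.3, 1.3), 100)
  expect_equal(percent_of_pre(0.94, 0.56), 59.574, tolerance = 1e-3)
  expect_equal(percent_of_pre(0.94, 0), 0)
  expect_error(percent_of_pre(0, 1), "positive")
})

test_that("circular ROI statistics match pixel enumeration", {
  const <- image_slice(matrix(7, 40, 40), 0.1)
  r <- roi_stats(const, c(20, 20), 1)
  expect_equal(r$mean, 7)
  expect_equal(r$sd, 0)

  # half-plane split through the ROI centre
  px <- matrix(2, 41, 41); px[, 22:41] <- 10
  hp <- image_slice(px, 0.1)
  rh <- roi_stats(hp, c(21.5, 21), 1.5)
  expect_equal(rh$mean, 6, tolerance = 0.15)

  # radius below half a pixel: single-pixel statistics
  r1 <- roi_stats(hp, c(10, 10), 0.02)
  expect_equal(r1$n_pixels, 1)
  expect_equal(r1$mean, 2)

  expect_error(roi_stats(const, c(2, 2), 1), "outside")
})

test_that("threshold detection uses at-or-above semantics", {
  conc <- c(2.2, 11.2, 44.8, 56)
  expect_equal(detect_threshold_concentration(conc, c(100, 100, 10, 10),
                                              100, 1, k = 3), 44.8)
  expect_true(is.na(detect_threshold_concentration(conc, rep(100, 4),
                                                   100, 1)))
  # non-monotone: a dark well followed by a bright one does not qualify
  nm <- detect_threshold_concentration(conc, c(10, 100, 100, 10), 100, 1)
  expect_equal(nm, 56)
  # oracle: exhaustive scan for the first index with all-dark suffix
  set.seed(3)
  for (i in 1:50) {
    means <- sample(c(10, 60, 100), 5, replace = TRUE)
    got <- detect_threshold_concentration(1:5, means, 100, 10, k = 3)
    dark <- means <= 100 - 30
    want <- NA_real_
    for (j in 5:1) { if (!all(dark[j:5])) break; want <- j }
    expect_identical(got, want)
  }
  expect_error(detect_threshold_concentration(numeric(0), numeric(0), 1, 0),
               "empty")
})

test_that("barrier group comparison assembles diffs, percentages and the rank test", {
  cond <- data.frame(pre_mm = c(1.0, 1.1, 0.9, 1.05),
                     post_mm = c(0.60, 0.64, 0.55, 0.62))
  unc <- data.frame(pre_mm = c(1.0, 0.95, 1.02, 1.1),
                    post_mm = c(0.87, 0.83, 0.90, 0.95))
  bc <- compare_barrier_groups(cond, unc)
  expect_equal(nrow(bc$joints), 8)
  expect_equal(bc$joints$diff_mm, bc$joints$pre_mm - bc$joints$post_mm)
  expect_equal(bc$joints$percent_of_pre,
               100 * bc$joints$post_mm / bc$joints$pre_mm)
  expect_equal(bc$test$H,
               oracle_kw_h(bc$joints$diff_mm, bc$joints$group))
  med <- bc$percent_summary
  expect_equal(med$median[med$group == "conditioned"],
               median(100 * cond$post_mm / cond$pre_mm))
  expect_error(compare_barrier_groups(cond[1, ], unc), "2 joints")
})
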