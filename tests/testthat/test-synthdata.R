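test_that("all generators are bit-reproducible under a fixed seed", {
  s1 <- generate_joint_phantom(joint_phantom_spec(noise_sd = 30, seed = 5))
  s2 <- generate_joint_phantom(joint_phantom_spec(noise_sd = 30, seed = 5))
  expect_identical(s1$pre$pixels, s2$pre$pixels)
  expect_identical(s1$post$pixels, s2$post$pixels)

  p1 <- generate_phantom_series(c(1, 2), function(c) 100, 500,
                                noise_sd = 5, seed = 9)
  p2 <- generate_phantom_series(c(1, 2), function(c) 100, 500,
                                noise_sd = 5, seed = 9)
  expect_identical(p1$slices[[1]]$pixels, p2$slices[[1]]$pixels)

  k1 <- generate_stack(stack_spec(n_live = 5, n_dead = 3,
                                  intensity_sd = 0.05, seed = 2))
  k2 <- generate_stack(stack_spec(n_live = 5, n_dead = 3,
                                  intensity_sd = 0.05, seed = 2))
  expect_identical(k1$green, k2$green)
  expect_identical(k1$truth, k2$truth)

  spp <- plate_spec(group_means = c(A = 10, B = 20),
                    group_sems = c(A = 1, B = 2),
                    group_ns = c(A = 4, B = 4), seed = 3)
  expect_identical(generate_plate(spp), generate_plate(spp))

  d1 <- generate_diameters(seed = 8)
  expect_identical(d1, generate_diameters(seed = 8))
})

test_that("joint phantom recovery matches the closed-form ground truth", {
  # no permeation: post equals pre (ratio 100%)
  ph0 <- generate_joint_phantom(joint_phantom_spec(permeation_depth = 0))
  m0 <- measure_barrier(ph0$pre, ph0$post, ph0$line)
  expect_equal(m0$percent_of_pre, 100)

  # linear rise, thickness 2 mm, permeation set for a 0.60 ratio
  spec <- joint_phantom_spec()
  spec$permeation_depth <- permeation_for_ratio(spec, 0.60)
  ph <- generate_joint_phantom(spec)
  m <- measure_barrier(ph$pre, ph$post, ph$line)
  expect_lt(abs(m$pre_mm - ph$truth$pre_mm), spec$pixel_spacing)
  expect_lt(abs(m$post_mm - ph$truth$post_mm), spec$pixel_spacing)
  expect_lt(abs(m$percent_of_pre - 60), 1.5)

  # gaussian-limb rise obeys its own closed form
  gs <- joint_phantom_spec(rise_shape = "gaussian-limb", rise_sigma = 0.5,
                           permeation_depth = 0.4)
  phg <- generate_joint_phantom(gs)
  mg <- measure_barrier(phg$pre, phg$post, phg$line)
  expect_equal(phg$truth$pre_mm, 0.5 * sqrt(2 * log(2)), tolerance = 1e-12)
  expect_lt(abs(mg$pre_mm - phg$truth$pre_mm), 2 * gs$pixel_spacing)
  expect_lt(abs(mg$post_mm - phg$truth$post_mm), 2 * gs$pixel_spacing)

  # deeper permeation never lengthens the recovered post distance
  post_d <- vapply(c(0, 0.3, 0.6, 0.9, 1.2), function(dep) {
    sp <- joint_phantom_spec(permeation_depth = dep)
    p <- generate_joint_phantom(sp)
    measure_barrier(p$pre, p$post, p$line)$post_mm
  }, numeric(1))
  expect_true(all(diff(post_d) <= 1e-9))

  expect_error(joint_phantom_spec(permeation_depth = 3),
               "permeation_depth")
  # unconditioned flag suppresses permeation
  phu <- generate_joint_phantom(spec, conditioned = FALSE)
  expect_equal(phu$truth$percent_of_pre, 100)
})

test_that("phantom series renders wells at the response value", {
  resp <- function(conc) 560 - 4 * conc
  ser <- generate_phantom_series(c(10, 50), resp, 560)
  for (i in 1:2) {
    w <- apply_window(ser$slices[[i]])
    roi <- roi_stats(w, ser$well_center, ser$well_radius_mm * 0.8)
    expected <- (resp(c(10, 50))[i] - (420 - 821 / 2)) / 821
    expect_equal(roi$mean, expected, tolerance = 1e-9)
  }
  expect_error(generate_phantom_series(numeric(0), resp, 560), "empty")
  expect_error(generate_phantom_series(c(2, 1), resp, 560), "ascending")
})

test_that("stack generation places and renders the requested spheres", {
  st <- generate_stack(stack_spec(n_live = 12, n_dead = 7, seed = 6))
  expect_equal(sum(st$truth$channel == "green"), 12)
  expect_equal(sum(st$truth$channel == "red"), 7)
  # pairwise separation holds across both channels
  xyz <- as.matrix(st$truth[, c("x_um", "y_um", "z_um")])
  dm <- as.matrix(dist(xyz))
  expect_gte(min(dm[upper.tri(dm)]), 8)
  # an over-packed volume fails after bounded retries
  expect_error(generate_stack(stack_spec(n_live = 500, n_dead = 0,
                                         dims_um = c(40, 40, 20), seed = 1)),
               "too small")
})

test_that("exact-moments plates reproduce their specification to machine precision", {
  set.seed(14)
  for (i in 1:15) {
    k <- sample(2:5, 1)
    gs <- LETTERS[1:k]
    means <- runif(k, 100, 20000)
    sems <- runif(k, 0, 3000)
    ns <- sample(2:10, k, replace = TRUE)
    sp <- plate_spec(group_means = setNames(means, gs),
                     group_sems = setNames(sems, gs),
                     group_ns = setNames(ns, gs),
                     replicate_sd = 100, seed = i)
    sm <- summarize_plate(generate_plate(sp))
    sm <- sm[match(gs, sm$group), ]
    expect_equal(sm$mean, means, tolerance = 1e-9)
    expect_equal(sm$sem, sems, tolerance = 1e-9)
  }
  expect_error(plate_spec(group_means = c(A = 1), group_sems = c(A = 0),
                          group_ns = c(A = 1)), "n >= 2")
  # zero-SEM equal-mean plate drives the ANOVA into its degenerate branch
  sp0 <- plate_spec(group_means = c(A = 5, B = 5), group_sems = c(A = 0, B = 0),
                    group_ns = c(A = 3, B = 3), seed = 1)
  per <- average_replicates(generate_plate(sp0))
  expect_error(anova_dunnett_style(per$fluorescence, per$group, control = "A"),
               "zero variance")
})

test_that("null plates hold the nominal ANOVA size", {
  set.seed(99)
  rej <- 0L
  n_sim <- 400L
  for (i in seq_len(n_sim)) {
    g <- rep(c("C", "T1", "T2"), each = 6)
    v <- rnorm(length(g), 1000, 150)
    rej <- rej + (anova_dunnett_style(v, g, control = "C")$p < 0.05)
  }
  expect_gt(rej / n_sim, 0.02)
  expect_lt(rej / n_sim, 0.09)
})

test_that("calibration series and TIFF/CSV round-trips preserve the data", {
  cal <- generate_calibration_series(loss_fraction = 0.44)
  expect_equal(mean_percent_discrepancy(cal$expected, cal$observed), 44)

  ph <- generate_joint_phantom(joint_phantom_spec(seed = 3))
  tf <- tempfile(fileext = ".tif")
  write_slice(ph$pre, tf, ground_truth = ph$truth)
  back <- read_slice(tf)
  expect_equal(back$pixel_spacing, ph$pre$pixel_spacing)
  expect_equal(back$wl, ph$pre$wl)
  # 16-bit quantisation of the 0..65535 range keeps greys within one step
  expect_lt(max(abs(back$pixels - ph$pre$pixels)), 1.01)
  expect_equal(attr(back, "ground_truth")$pre_mm, ph$truth$pre_mm)

  st <- generate_stack(stack_spec(n_live = 4, n_dead = 2, seed = 5))
  ts <- tempfile(fileext = ".tif")
  write_stack(st, ts)
  st2 <- read_stack(ts)
  expect_equal(dim(st2$green), dim(st$green))
  expect_lt(max(abs(st2$green - st$green)), 1 / 65535 * max(st$green) + 1e-9)
  expect_equal(st2$voxel_size, st$voxel_size)

  tab <- data.frame(group = c("C", "H"), sample = c("a", "b"),
                    fluorescence = c(1.25, 3.5))
  tc <- tempfile(fileext = ".csv")
  write_table_csv(tab, tc)
  expect_equal(read_table_csv(tc), tab)
  unlink(c(tf, paste0(tf, ".json"), ts, paste0(ts, ".json"), tc))
})
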