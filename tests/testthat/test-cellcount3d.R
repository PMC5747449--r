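test_that("empty and degenerate channels are handled", {
  st <- generate_stack(stack_spec(n_live = 5, n_dead = 0, seed = 4))
  det <- detect_cells(st, "red")
  expect_equal(nrow(det), 0)
  cc <- count_cells(st)
  expect_equal(cc$dead_count, 0)
  expect_equal(cc$live_fraction, 100)
  # diameter under two voxels along an axis is rejected
  expect_error(detect_cells(st, "red",
                            detection_settings(dead_diameter = 3)),
               "too coarse")
})

test_that("a single noise-free sphere is localized within one voxel", {
  sp <- stack_spec(n_live = 1, n_dead = 0, dims_um = c(60, 60, 40), seed = 11)
  st <- generate_stack(sp)
  det <- detect_cells(st, "green")
  expect_equal(nrow(det), 1)
  tru <- st$truth[st$truth$channel == "green", ]
  expect_lt(sqrt((det$x_um - tru$x_um)^2 + (det$y_um - tru$y_um)^2 +
                 (det$z_um - tru$z_um)^2), sqrt(3) * 2)
})

test_that("detection is equivariant under whole-voxel translation", {
  sp <- stack_spec(n_live = 3, n_dead = 0, dims_um = c(80, 80, 40), seed = 13)
  st <- generate_stack(sp)
  det <- detect_cells(st, "green")
  shift <- c(3L, 2L, 1L)  # voxels
  arr <- st$green
  d <- dim(arr)
  shifted <- array(0, d)
  shifted[(1 + shift[1]):d[1], (1 + shift[2]):d[2], (1 + shift[3]):d[3]] <-
    arr[1:(d[1] - shift[1]), 1:(d[2] - shift[2]), 1:(d[3] - shift[3])]
  det_s <- detect_cells(shifted, "green", voxel_size = st$voxel_size)
  expect_equal(nrow(det_s), nrow(det))
  o <- order(det$x_um); os <- order(det_s$x_um)
  expect_equal(det_s$x_um[os], det$x_um[o] + shift[1] * st$voxel_size[1])
  expect_equal(det_s$y_um[os], det$y_um[o] + shift[2] * st$voxel_size[2])
  expect_equal(det_s$z_um[os], det$z_um[o] + shift[3] * st$voxel_size[3])
})

test_that("tile-split detection with suppression merging conserves counts", {
  sp <- stack_spec(n_live = 20, n_dead = 0, seed = 17)
  st <- generate_stack(sp)
  whole <- detect_cells(st, "green")
  d <- dim(st$green)
  cut <- floor(d[3] / 2)
  overlap <- 6L
  tile1 <- st$green[, , 1:(cut + overlap)]
  tile2 <- st$green[, , (cut - overlap + 1):d[3]]
  d1 <- detect_cells(tile1, "green", voxel_size = st$voxel_size)
  d2 <- detect_cells(tile2, "green", voxel_size = st$voxel_size)
  d2$z_um <- d2$z_um + (cut - overlap) * st$voxel_size[3]
  merged <- merge_detections(rbind(d1, d2), 0.7 * 8)
  expect_equal(nrow(merged), nrow(whole))
})

test_that("viability arithmetic and pooling bounds", {
  expect_equal(viability(30, 20), 60)
  expect_equal(viability(17, 0), 100)
  expect_equal(viability(0, 9), 0)
  expect_error(viability(0, 0), "no cells")
  # pooled viability lies between the parts
  v1 <- viability(30, 20); v2 <- viability(5, 15)
  vp <- viability(35, 35)
  expect_true(vp >= min(v1, v2) && vp <= max(v1, v2))
})

test_that("manual review edits counts with an audit trail", {
  st <- generate_stack(stack_spec(n_live = 30, n_dead = 20, seed = 4))
  cc <- count_cells(st)
  expect_equal(c(cc$live_count, cc$dead_count), c(30, 20))
  # no edits: identity
  expect_identical(manual_review(cc), cc)
  rm_dead <- cc$dead_centers[1, c("x_um", "y_um", "z_um")]
  edited <- manual_review(cc, add_live = data.frame(x_um = 5, y_um = 5,
                                                    z_um = 5),
                          remove_dead = rm_dead)
  expect_equal(c(edited$live_count, edited$dead_count), c(31, 19))
  expect_equal(edited$live_fraction, 62)
  expect_length(edited$edits, 1)
  # removing the same centre again has nothing left to match
  expect_error(manual_review(edited, remove_dead = rm_dead), "no match")
  expect_error(manual_review(cc, remove_live = data.frame(x_um = -50,
                                                          y_um = -50,
                                                          z_um = -50)),
               "no match")
})

test_that("recovered live fraction tracks the generated ratio under noise", {
  set.seed(23)
  fr <- vapply(1:5, function(i) {
    st <- generate_stack(stack_spec(n_live = 30, n_dead = 20,
                                    intensity_sd = 0.08,
                                    seed = 100 + i))
    count_cells(st)$live_fraction
  }, numeric(1))
  expect_lt(abs(mean(fr) - 60), 2)
})
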