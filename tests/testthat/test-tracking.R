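test_that("uniform field yields a straight full-length streamline", {
  f <- straight_field(ny = 700)
  seed <- center_seed_mask(f$grid)
  p <- tracking_params(qa_threshold = 0.1, seed_count = 5, rng_seed = 3)
  tr <- track_streamlines(f, p, seed)
  expect_gt(n_streamlines(tr), 0)
  lens <- streamline_lengths(tr)
  # the grid is long enough that only the length cap can stop the track
  expect_true(all(abs(lens - p$max_length_mm) <= 2 * p$step_mm))
  for (i in seq_len(n_streamlines(tr))) {
    pts <- streamline_points(tr, i)
    expect_lt(max(abs(pts[, 1] - pts[1, 1])), 1e-6)
    expect_lt(max(abs(pts[, 3] - pts[1, 3])), 1e-6)
  }
})

test_that("a QA wall stops every streamline before it", {
  gap <- 100:103   # interpolation reaches zero only inside a thick wall
  f <- straight_field(ny = 140, qa_gap = gap)
  seed <- center_seed_mask(f$grid)
  p <- tracking_params(qa_threshold = 0.1, seed_count = 20, rng_seed = 3,
                       min_length_mm = 10)
  tr <- track_streamlines(f, p, seed)
  wall_y <- voxel_to_world(f$grid, c(0, gap[1] - 1, 0))[1, 2]
  for (i in seq_len(n_streamlines(tr)))
    expect_lt(max(streamline_points(tr, i)[, 2]), wall_y + p$step_mm)
})

test_that("tracking is deterministic and respects its contract bounds", {
  f <- tiny_field()
  masks <- make_region_masks(tiny_spec(), "left")
  p <- tracking_params(qa_threshold = 1e-3, seed_count = 800, rng_seed = 5)
  tr1 <- track_streamlines(f, p, masks$seed_mask)
  tr2 <- track_streamlines(f, p, masks$seed_mask)
  expect_identical(tr1$coords, tr2$coords)
  expect_lte(n_streamlines(tr1), p$seed_count)
  lens <- streamline_lengths(tr1)
  expect_true(all(lens >= p$min_length_mm - 1e-9))
  expect_true(all(lens <= p$max_length_mm + 1e-9))
  expect_lte(max_turn_deg(tr1), p$angular_threshold_deg + 1e-6)
  # spacing between consecutive points never exceeds twice the step
  d <- diff(tr1$coords)
  seg <- sqrt(rowSums(d^2))
  joints <- cumsum(tr1$npts)
  seg <- seg[-joints[-length(joints)]]
  expect_lte(max(seg), 2 * p$step_mm)
})

test_that("an all-zero field warns and returns an empty set", {
  g <- volume_grid(c(5, 5, 5))
  f <- orientation_field(array(0, c(g$shape, 3)), array(0, g$shape), g)
  seed <- center_seed_mask(g)
  expect_warning(tr <- track_streamlines(
    f, tracking_params(0.1, seed_count = 10), seed), "all zero")
  expect_equal(n_streamlines(tr), 0L)
})

test_that("ROI filtering keeps passers-through and enforces lengths", {
  g <- volume_grid(c(5, 40, 5))
  mk <- function(ys) streamline_set(cbind(2, ys, 2), npts = length(ys))
  tracks <- concat_streamlines(list(
    mk(seq(0, 35, by = 0.5)),   # long, passes ROI
    mk(seq(0, 35, by = 0.5) ) , # duplicate long
    mk(seq(0, 8, by = 0.5))))   # short
  roi <- array(0L, g$shape)
  roi[, 31, ] <- 1L
  roi_vol <- label_volume(roi, g)
  out <- filter_streamlines(tracks, roi_vol, "ORu", min_length_mm = 30)
  expect_equal(n_streamlines(out), 2L)
  expect_true(all(out$tags$subdivision == "ORu"))
  # 29.9 mm track with min 30 is removed even through the ROI
  sh <- mk(seq(1, 30.9, by = 0.5))
  expect_equal(n_streamlines(
    filter_streamlines(sh, roi_vol, min_length_mm = 30)), 0L)
  # ROI = whole grid restricts by length only
  all_roi <- label_volume(array(1L, g$shape), g)
  out2 <- filter_streamlines(tracks, all_roi, min_length_mm = 30)
  expect_equal(n_streamlines(out2), 2L)
  expect_warning(filter_streamlines(tracks, label_volume(array(0L, g$shape), g)),
                 "empty")
})

test_that("the QA threshold heuristic concentrates mass inside the mask", {
  f <- tiny_field()
  expect_equal(suggest_qa_threshold(f, f$qa > 0), 0)
  # constructed case: low-QA signal outside the tissue forces the threshold
  # just above it
  g <- volume_grid(c(3, 3, 3))
  qa <- array(0, g$shape)
  qa[1:2, 1:2, 1:2] <- 0.9      # inside tissue
  qa[3, 3, 3] <- 0.2            # stray signal outside
  dir <- array(0, c(g$shape, 3))
  dir[, , , 2] <- ifelse(qa > 0, 1, 0)
  f2 <- orientation_field(dir, qa, g)
  tissue <- array(FALSE, g$shape)
  tissue[1:2, 1:2, 1:2] <- TRUE
  expect_equal(suggest_qa_threshold(f2, tissue), 0.9)
})
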