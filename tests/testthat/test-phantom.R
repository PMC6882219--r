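test_that("noise-free bundle crests exactly at the prescribed ridge", {
  spec <- tiny_spec(n = 20, jitter_sd = 0, twist_gain = 0)
  for (side in c("left", "right")) {
    b <- make_phantom_bundle(spec, side)
    expect_equal(max(b$coords[, 2]), loop_apex_y(spec, side))
    # every streamline starts within 1 mm of the LGN
    off <- c(0, cumsum(b$npts))
    starts <- b$coords[off[-length(off)] + 1, ]
    d <- sqrt(rowSums(sweep(starts, 2, spec$lgn_center[[side]])^2))
    expect_lt(max(d), 1)
  }
})

test_that("bundle generation is deterministic under the seed", {
  s <- tiny_spec(n = 10)
  b1 <- make_phantom_bundle(s, "left")
  b2 <- make_phantom_bundle(s, "left")
  expect_identical(b1$coords, b2$coords)
  b3 <- make_phantom_bundle(tiny_spec(n = 10, rng_seed = 7L), "left")
  expect_false(identical(b1$coords, b3$coords))
})

test_that("twist gain controls the centroid crossover count", {
  b <- make_phantom_bundle(tiny_spec(n = 150), "left")
  tw <- twist_profile(b, "left")
  expect_equal(tw$sign_changes, 1L)
  b0 <- make_phantom_bundle(tiny_spec(n = 150, twist_gain = 0), "left")
  expect_equal(twist_profile(b0, "left")$sign_changes, 0L)
  # brute-force recount of the profile's sign structure
  d <- tw$profile$diff_lateral
  d <- d[abs(d) > 1]
  expect_equal(sum(diff(sign(d)) != 0), 1L)
})

test_that("degenerate phantom geometry is rejected", {
  expect_error(phantom_spec(dtm_mm = c(left = 60, right = 23)),
               "anterior to the LGN")
  expect_error(phantom_spec(dtm_mm = c(left = -5, right = 23)),
               "posterior to the temporal tip")
})

test_that("rasterized field has unit directions and count-scaled QA", {
  f <- tiny_field()
  expect_true(all(f$qa >= 0))
  expect_equal(max(f$qa), 1)
  n2 <- sqrt(apply(f$dir^2, 1:3, sum))
  expect_true(all(abs(n2[f$qa > 0] - 1) < 1e-9))
  expect_true(all(n2[f$qa == 0] == 0))
})

test_that("QA equals per-voxel distinct-streamline counts (brute force)", {
  s <- tiny_spec(n = 6)
  b <- subset_streamlines(make_phantom_bundle(s, "left"), 1:8)
  f <- rasterize_orientation_field(b, s$grid)
  counts <- integer(prod(s$grid$shape))
  for (v in brute_streamline_voxels(b, s$grid)) counts[v] <- counts[v] + 1L
  expect_equal(as.vector(f$qa) * max(counts), as.numeric(counts),
               tolerance = 1e-12)
})

test_that("single straight streamline rasterizes to its own direction", {
  g <- volume_grid(c(5, 20, 5))
  b <- streamline_set(cbind(2, seq(1, 18, by = 0.4), 2),
                      npts = length(seq(1, 18, by = 0.4)))
  f <- rasterize_orientation_field(b, g)
  set <- which(f$qa > 0)
  dirs <- matrix(f$dir, ncol = 3)[set, , drop = FALSE]
  expect_true(all(abs(abs(dirs[, 2]) - 1) < 1e-9))
  expect_true(all(f$qa[set] == 1))
})

test_that("bundles outside the grid are refused with the extent named", {
  g <- volume_grid(c(5, 5, 5))
  b <- streamline_set(cbind(c(0, 30), c(0, 30), c(0, 30)), npts = 2L)
  expect_error(rasterize_orientation_field(b, g), "outside the grid")
})

test_that("region masks are disjoint and the tip is anterior to the ridge", {
  spec <- tiny_spec()
  m <- make_region_masks(spec, "left")
  overlap <- m$seed_mask$data * m$roi_upper_mask$data +
    m$seed_mask$data * m$roi_lower_mask$data +
    m$roi_upper_mask$data * m$roi_lower_mask$data
  expect_true(all(overlap == 0))
  expect_gt(m$temporal_tip_landmark[2], loop_apex_y(spec, "left"))
  # seed sphere voxel count close to the analytic sphere volume
  vol_mm <- sum(m$seed_mask$data) * prod(voxel_sizes(spec$grid))
  expect_lt(abs(vol_mm - 4 / 3 * pi * 5^3) / (4 / 3 * pi * 5^3), 0.25)
})

test_that("seed sphere voxel count matches the sphere volume on a fine grid", {
  g <- volume_grid(c(31, 31, 31), {
    a <- diag(4); a[1:3, 4] <- c(-15, -15, -15); a
  })
  ctr <- grid_voxel_centers(g)
  inside <- sqrt(rowSums(ctr^2)) <= 2
  expect_lt(abs(sum(inside) * 1 - 4 / 3 * pi * 8) / (4 / 3 * pi * 8), 0.1)
})

test_that("cohort records truth and maps landmarks through the transforms", {
  spec <- tiny_spec(n = 15)
  coh <- make_cohort(3, spec, rasterize = FALSE)
  expect_length(coh$truth$transforms, 3)
  expect_equal(dim(coh$truth$subject_dtm), c(2L, 3L))
  for (i in 1:3) {
    t_i <- coh$truth$transforms[[i]]
    apex_t <- apply_to_points(t_i, coh$truth$template_apex$left,
                              warn_outside = FALSE)
    expect_equal(unname(coh$subjects[[i]]$landmarks$left$apex),
                 unname(apex_t[1, ]), tolerance = 1e-9)
  }
  # identity cohort reproduces the template field
  coh0 <- make_cohort(1, spec,
                      deform = list(max_rot_deg = 0, max_scale_dev = 0,
                                    max_shift_mm = 0, warp_amp_mm = 0))
  tmpl_field <- rasterize_orientation_field(coh$truth$template_bundle,
                                            spec$grid)
  expect_equal(coh0$subjects[[1]]$field$qa, tmpl_field$qa)
})

test_that("subject transforms are reproducible and amplitude-bounded", {
  g <- default_phantom_grid(3)
  t1 <- make_subject_transform(11, grid = g)
  t2 <- make_subject_transform(11, grid = g)
  expect_identical(t1$affine, t2$affine)
  expect_identical(t1$displacement, t2$displacement)
  mag <- sqrt(rowSums(matrix(t1$displacement, ncol = 3)^2))
  expect_lte(max(mag), 2.5 + 1e-9)
  t0 <- make_subject_transform(11, 0, 0, 0, 0, grid = g)
  expect_equal(t0$affine, diag(4))
  expect_null(t0$displacement)
})

test_that("phantom config file round-trips into a spec", {
  cfg <- tempfile(fileext = ".yaml")
  writeLines(c("dtm_left: 24.5", "fan_half_angle: 9", "n_streamlines: 12",
               "rng_seed: 5"), cfg)
  s <- phantom_spec_from_config(cfg)
  expect_equal(s$dtm_mm[["left"]], 24.5)
  expect_equal(s$fan_half_angle, 9)
  expect_equal(s$n_streamlines, 12)
  expect_equal(s$rng_seed, 5L)
  expect_equal(s$dtm_mm[["right"]], 26.41)
})
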