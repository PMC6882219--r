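test_that("middle-third slab spans the central Y interval", {
  g <- volume_grid(c(5, 31, 5))
  tdi <- array(0L, g$shape)
  tdi[3, 1:31, 3] <- 1L          # bar spanning y 0..30
  bar <- tdi_volume(tdi, g)
  slab <- middle_third_slab(bar)
  ys <- grid_voxel_centers(g)[, 2][as.vector(slab)]
  expect_gte(min(ys), 10)
  expect_lte(max(ys), 20)
  expect_lte(sum(slab), sum(tdi > 0))
  expect_equal(sum(slab), 11)   # 31 slices / 3, inclusive bounds
  expect_error(middle_third_slab(tdi_volume(array(0L, g$shape), g)), "empty")
})

test_that("maximal-density voxels equal the exhaustive per-slice scan", {
  set.seed(11)
  g <- volume_grid(c(12, 15, 12))
  for (rep in 1:5) {
    tdi <- tdi_volume(array(rpois(prod(g$shape), 1.2), g$shape), g)
    slab <- array(TRUE, g$shape)
    slab[, 1:4, ] <- FALSE
    expect_identical(sort(max_density_voxels(tdi, slab)),
                     brute_max_density(tdi, slab))
  }
  # tie case: both maxima included
  tdi <- array(0L, g$shape)
  tdi[3, 7, 3] <- 7L; tdi[9, 7, 9] <- 7L; tdi[5, 7, 5] <- 3L
  mv <- max_density_voxels(tdi_volume(tdi, g), array(TRUE, g$shape))
  expect_length(mv, 2L)
  # global variant returns the overall argmax set
  tdi[3, 8, 3] <- 9L
  mv_g <- max_density_voxels(tdi_volume(tdi, g), array(TRUE, g$shape),
                             per_slice = FALSE)
  expect_length(mv_g, 1L)
})

test_that("correspondence rate counts containment in side labels", {
  g <- volume_grid(c(6, 6, 6))
  lab <- array(0L, g$shape)
  lab[1:3, , ] <- 1L
  labels <- label_volume(lab, g)
  inside <- which(lab == 1L)[1:10]
  outside <- which(lab == 0L)[1:10]
  expect_equal(correspondence_rate(inside, labels, "left"), 1)
  expect_equal(correspondence_rate(outside, labels, "left"), 0)
  expect_equal(correspondence_rate(c(inside, outside), labels, "left"), 0.5)
  expect_equal(correspondence_rate(inside, labels, "right"), 0)
  expect_error(correspondence_rate(integer(), labels, "left"), "empty")
})

test_that("shift profile is consistent at zero and dies beyond the labels", {
  spec <- tiny_spec(n = 60)
  b <- make_phantom_bundle(spec, "left")
  b$tags$subject <- "s1"
  lab <- build_label_volume(split_divisions(b), spec$grid)
  tdi <- compute_tdi(b, spec$grid)
  pr <- shifted_cr_profile(tdi, lab, "left", max_offset_mm = 40)
  slab <- middle_third_slab(tdi, "left")
  mv <- max_density_voxels(tdi, slab)
  expect_equal(pr$cr0, correspondence_rate(mv, lab, "left"))
  df <- pr$profile
  expect_equal(df$cr[df$offset_mm == 0], pr$cr0)
  # beyond the intersection transition the CR is exactly zero
  expect_equal(df$cr[1], 0)
  expect_equal(df$cr[nrow(df)], 0)
  expect_false(df$intersects[1])
  expect_true(all(is.finite(pr$tolerable_cr)))
  # warning when the range never leaves the labels
  expect_warning(shifted_cr_profile(tdi, lab, "left", max_offset_mm = 2),
                 "transition")
})

test_that("bootstrap CI is reproducible, degenerate-safe and shrinks as 1/sqrt(n)", {
  x <- c(0.7, 0.8, 0.9, 0.85, 0.75, 0.95, 0.6, 0.88)
  b1 <- bootstrap_mean_ci(x, n_boot = 2000, rng_seed = 3)
  b2 <- bootstrap_mean_ci(x, n_boot = 2000, rng_seed = 3)
  expect_identical(b1, b2)
  expect_true(b1$ci_low <= b1$mean && b1$mean <= b1$ci_high)
  bc <- bootstrap_mean_ci(c(0.8, 0.8, 0.8))
  expect_equal(c(bc$ci_low, bc$ci_high), c(0.8, 0.8))
  expect_true(bc$mean_inside)
  widths <- sapply(c(10, 40, 160), function(n) {
    set.seed(1)
    v <- rnorm(n, 0.8, 0.1)
    b <- bootstrap_mean_ci(v, n_boot = 4000, rng_seed = 2)
    b$ci_high - b$ci_low
  })
  ratio <- widths[1:2] / widths[2:3]
  expect_true(all(ratio > 1.5 & ratio < 2.7)) # ~2 expected per 4x n
})

test_that("safety zone dilates by a Euclidean margin and flags containment", {
  g <- volume_grid(c(20, 20, 20))
  lab <- array(0L, g$shape)
  lab[9:12, 9:12, 9:12] <- 1L
  labels <- label_volume(lab, g)
  mv_inside <- which(lab == 1L)[1:5]
  # margin 0 reduces to exact containment, i.e. CR == 1
  s0 <- safety_zone_check(labels, "left", mv_inside, margin_mm = 0)
  expect_true(s0$pass)
  expect_identical(s0$margin_mask, lab == 1L)
  # a 3 mm mislocalized voxel fails CR but stays inside the 5 mm zone
  v3 <- oratlas:::voxel_linear_index(g$shape, c(12 + 3, 10, 10) - 1) # 3 mm lateral
  expect_equal(correspondence_rate(v3, labels, "left"), 0)
  s5 <- safety_zone_check(labels, "left", v3, margin_mm = 5)
  expect_true(s5$pass)
  s1 <- safety_zone_check(labels, "left", v3, margin_mm = 1)
  expect_false(s1$pass)
  # dilation is monotone and matches the exact distance threshold
  expect_true(all(s5$margin_mask[lab == 1L]))
  ctr <- grid_voxel_centers(g)
  labpts <- ctr[lab == 1L, ]
  dmin <- apply(ctr[as.vector(s5$margin_mask), , drop = FALSE], 1, function(p)
    min(sqrt(colSums((t(labpts) - p)^2))))
  expect_lte(max(dmin), 5)
})

test_that("required sample size matches noncentral-t power and is monotone", {
  # the one-sample design: tested mean 75%, tolerable mean 4%, SD 10%
  expect_equal(required_sample_size(75, 4, 10), 3L)
  expect_equal(required_sample_size(1e6, 0, 1), 2L) # huge effect floor
  # cross-check against stats::power.t.test at the boundary
  expect_gte(power.t.test(n = 3, delta = 71, sd = 10,
                          type = "one.sample")$power, 0.90)
  expect_lt(power.t.test(n = 2, delta = 71, sd = 10,
                         type = "one.sample")$power, 0.90)
  # halving the effect never decreases n; growing sd never decreases n
  ns <- sapply(c(71, 35.5, 17.75, 8.9), function(d)
    required_sample_size(d, 0, 10))
  expect_true(all(diff(ns) >= 0))
  ns_sd <- sapply(c(5, 10, 20), function(s) required_sample_size(20, 0, s))
  expect_true(all(diff(ns_sd) >= 0))
  expect_error(required_sample_size(1, 0, 1000, n_max = 50), "unreachable")
})

test_that("voxel_linear_index agrees with R array indexing", {
  sh <- c(4L, 5L, 6L)
  arr <- array(seq_len(prod(sh)), sh)
  expect_equal(arr[2, 3, 4], oratlas:::voxel_linear_index(sh, c(1, 2, 3)))
})
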