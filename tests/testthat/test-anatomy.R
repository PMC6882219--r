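test_that("anterior ridge sits at the prescribed crest on clean phantoms", {
  spec <- tiny_spec(n = 20, jitter_sd = 0)
  b <- make_phantom_bundle(spec, "left")
  ridge <- anterior_ridge(b, "left", lgn_y = spec$lgn_center$left[2])
  expect_equal(unname(ridge[2]), loop_apex_y(spec, "left"))
  # region-based and track-based ridge agree within one voxel
  tdi <- compute_tdi(b, spec$grid)
  ridge_v <- anterior_ridge(tdi, "left", lgn_y = spec$lgn_center$left[2])
  expect_lt(abs(ridge_v[2] - ridge[2]), max(voxel_sizes(spec$grid)))
  # nothing anterior to the LGN plane is an error
  expect_error(anterior_ridge(b, "left", lgn_y = 50), "anterior")
})

test_that("raising the crest never lowers the measured ridge", {
  ys2 <- sapply(c(26, 23, 20), function(dtm) {
    s <- tiny_spec(n = 10, jitter_sd = 0, dtm_mm = c(left = dtm, right = 26.41))
    anterior_ridge(make_phantom_bundle(s, "left"), "left")[2]
  })
  expect_true(all(diff(ys2) > 0))
})

test_that("dTM and LGN-to-ridge distances follow their definitions", {
  expect_equal(measure_dtm(c(0, 50, 0), c(5, 26.9, -3)), 23.1)
  expect_equal(measure_dtm(c(1, 10, 2), c(1, 10, 2)), 0)
  expect_equal(measure_dtm(c(0, 50, 0), c(0, 20, 40), euclidean = TRUE), 50)
  expect_equal(lgn_to_ridge_distance(c(0, 0, 0), c(0, 40.7, 0)), 40.7)
  expect_equal(lgn_to_ridge_distance(c(1, 2, 3), c(1, 2, 3)), 0)
  # rigid invariance of the Euclidean distance
  set.seed(6)
  for (i in 1:5) {
    r <- oratlas:::rot_axis(sample(3, 1), runif(1, -180, 180))
    shift <- runif(3, -20, 20)
    a <- c(runif(3, -10, 10)); b <- c(runif(3, -10, 10))
    expect_equal(lgn_to_ridge_distance(r %*% a + shift, r %*% b + shift),
                 lgn_to_ridge_distance(a, b), tolerance = 1e-9)
  }
})

test_that("twist profile works on labels as well as tracks", {
  spec <- tiny_spec(n = 60)
  b <- make_phantom_bundle(spec, "left")
  b$tags$subject <- "s1"
  lab <- build_label_volume(split_divisions(b), spec$grid)
  tw <- twist_profile(lab, "left")
  expect_equal(tw$sign_changes, 1L)
  expect_true(all(c("y_mm", "x_ORu", "x_ORl", "diff_lateral") %in%
                    names(tw$profile)))
  # profile rows only where both divisions are present
  expect_true(all(is.finite(tw$profile$diff_lateral)))
  expect_error(twist_profile(subset_streamlines(b, b$tags$subdivision == "ORu"),
                             "left"), "absent")
})

test_that("geometry report recovers the generative dTM per side", {
  spec <- tiny_spec(n = 40)
  for (side in c("left", "right")) {
    b <- make_phantom_bundle(spec, side)
    rep <- geometry_report(b, side, spec$lgn_center[[side]],
                           spec$temporal_tip[[side]])
    expect_lt(abs(rep$dtm_mm - spec$dtm_mm[[side]]), 1)
    expect_gt(rep$lgn_to_ridge_mm, 20)
    expect_equal(rep$twist$sign_changes, 1L)
  }
})
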