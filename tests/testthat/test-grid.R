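test_that("voxel/world round trips follow the affine", {
  aff <- diag(c(1.5, 2, 2.5, 1))
  aff[1:3, 4] <- c(-10, -20, 5)
  g <- volume_grid(c(10, 12, 8), aff)
  expect_equal(voxel_to_world(g, c(0, 0, 0))[1, ], c(-10, -20, 5))
  expect_equal(voxel_to_world(g, c(2, 3, 4))[1, ], c(-7, -14, 15))
  p <- matrix(runif(30, -5, 5), ncol = 3)
  expect_equal(world_to_voxel(g, voxel_to_world(g, p)), p, tolerance = 1e-12)
  expect_equal(voxel_sizes(g), c(1.5, 2, 2.5))
})

test_that("degenerate grids and volumes are rejected", {
  expect_error(volume_grid(c(4, 4, 4), matrix(0, 4, 4)), "invertible")
  g <- volume_grid(c(3, 3, 3))
  expect_error(label_volume(array(7L, c(3, 3, 3)), g), "outside 0..4")
  expect_error(tdi_volume(array(-1L, c(3, 3, 3)), g), "non-negative")
})

test_that("atlas legend maps sides to label codes", {
  expect_equal(unname(atlas_legend()), 1:4)
  expect_equal(side_labels("left"), c(1L, 3L))
  expect_equal(side_labels("right"), c(2L, 4L))
})

test_that("streamline container bookkeeping holds", {
  coords <- rbind(c(0, 0, 0), c(0, 1, 0), c(0, 2, 0),
                  c(5, 5, 5), c(5, 8, 9))
  s <- streamline_set(coords, c(3L, 2L),
                      tags = data.frame(subdivision = c("ORu", "ORl")))
  expect_equal(n_streamlines(s), 2L)
  expect_equal(streamline_points(s, 2), coords[4:5, ])
  expect_equal(streamline_lengths(s), c(2, 5))
  s2 <- subset_streamlines(s, 2)
  expect_equal(s2$coords, coords[4:5, , drop = FALSE])
  expect_equal(s2$tags$subdivision, "ORl")
  cc <- concat_streamlines(list(s, s2))
  expect_equal(n_streamlines(cc), 3L)
  expect_equal(streamline_lengths(cc), c(2, 5, 5))
  expect_error(streamline_set(coords, c(2L, 2L)), "sum")
})
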