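test_that("point mapping covers identity, translation and warnings", {
  expect_equal(apply_to_points(identity_transform(), rbind(c(1, 2, 3))),
               rbind(c(1, 2, 3)))
  a <- diag(4); a[1, 4] <- 2
  p <- matrix(runif(30), ncol = 3)
  expect_equal(apply_to_points(spatial_transform(a), p),
               p + rep(c(2, 0, 0), each = 10))
  g <- volume_grid(c(4, 4, 4))
  disp <- array(0, c(g$shape, 3)); disp[, , , 1] <- 1
  t <- spatial_transform(diag(4), disp, g)
  expect_warning(out <- apply_to_points(t, rbind(c(50, 50, 50))), "outside")
  expect_equal(out, rbind(c(50, 50, 50))) # zero displacement out there
})

test_that("composition matches sequential application", {
  set.seed(9)
  rand_aff <- function() {
    a <- diag(4)
    a[1:3, 1:3] <- oratlas:::rot_axis(3, runif(1, -20, 20)) %*%
      diag(runif(3, 0.9, 1.1))
    a[1:3, 4] <- runif(3, -5, 5)
    a
  }
  p <- matrix(runif(60, -10, 10), ncol = 3)
  t1 <- spatial_transform(rand_aff())
  t2 <- spatial_transform(rand_aff())
  t3 <- spatial_transform(rand_aff())
  expect_equal(apply_to_points(compose_transforms(t1, t2), p),
               apply_to_points(t1, apply_to_points(t2, p)), tolerance = 1e-9)
  lhs <- compose_transforms(compose_transforms(t1, t2), t3)
  rhs <- compose_transforms(t1, compose_transforms(t2, t3))
  expect_equal(apply_to_points(lhs, p), apply_to_points(rhs, p),
               tolerance = 1e-6)
  # two pure translations sum
  tr <- function(v) { a <- diag(4); a[1:3, 4] <- v; spatial_transform(a) }
  expect_equal(compose_transforms(tr(c(1, 2, 3)), tr(c(4, 0, -1)))$affine[1:3, 4],
               c(5, 2, 2))
  # composition with a dense field stays within interpolation tolerance
  g <- default_phantom_grid(4)
  tw <- make_subject_transform(3, grid = g)
  comp <- compose_transforms(tw, tr(c(2, 0, 0)))
  q <- matrix(runif(60, -20, 10), ncol = 3)
  expect_lt(max(abs(apply_to_points(comp, q, warn_outside = FALSE) -
                    apply_to_points(tw, q + rep(c(2, 0, 0), each = 20),
                                    warn_outside = FALSE))), 0.05)
})

test_that("inversion is exact for affines and accurate for fields", {
  a <- diag(4)
  a[1:3, 1:3] <- oratlas:::rot_axis(1, 12) %*% diag(c(1.1, 0.95, 1))
  a[1:3, 4] <- c(3, -2, 1)
  t <- spatial_transform(a)
  inv <- invert_transform(t)
  expect_equal(inv$affine %*% a, diag(4), tolerance = 1e-12)
  expect_equal(invert_transform(identity_transform())$affine, diag(4))
  g <- volume_grid(c(30, 30, 20), {
    a <- diag(c(2, 2, 2, 1)); a[1:3, 4] <- c(-30, -30, -20); a
  })
  tw <- make_subject_transform(21, warp_amp_mm = 3, warp_scale_mm = 15,
                               grid = g)
  inv_w <- invert_transform(tw, upsample = 4L)
  ctr <- grid_voxel_centers(g)
  keep <- seq(1, nrow(ctr), by = 7)
  rt <- apply_to_points(inv_w, apply_to_points(tw, ctr[keep, ],
                                               warn_outside = FALSE),
                        warn_outside = FALSE)
  expect_lt(max(sqrt(rowSums((rt - ctr[keep, ])^2))), 0.05)
})

test_that("label resampling is exact for identity and voxel shifts", {
  spec <- tiny_spec(n = 12)
  b <- make_phantom_bundle(spec, "left")
  b$tags$subject <- "s1"
  lab <- build_label_volume(split_divisions(b), spec$grid)
  out <- resample_labels(lab, identity_transform(), spec$grid)
  expect_identical(out$data, lab$data)
  # translation by exactly one voxel: brute-force shifted comparison
  vs <- voxel_sizes(spec$grid)
  shifted <- translate_labels(lab, c(vs[1], 0, 0))
  manual <- array(0L, spec$grid$shape)
  manual[-1, , ] <- lab$data[-spec$grid$shape[1], , ]
  expect_identical(shifted$data, manual)
  expect_true(all(unique(as.vector(shifted$data)) %in% 0:4))
  # conservation away from the boundary
  expect_equal(sum(shifted$data == 1), sum(lab$data[-spec$grid$shape[1], , ] == 1))
})

test_that("pull-back round trip restores labels on smooth warps", {
  spec <- tiny_spec(n = 60)
  b <- concat_streamlines(list(make_phantom_bundle(spec, "left"),
                               make_phantom_bundle(spec, "right")))
  b$tags$subject <- "s1"
  lab <- build_label_volume(split_divisions(b), spec$grid)
  t <- make_subject_transform(5, grid = spec$grid)
  r1 <- resample_labels(lab, t, spec$grid)
  r2 <- resample_labels(r1, invert_transform(t, upsample = 2L), spec$grid)
  nz <- which(lab$data != 0)
  expect_gt(mean(r2$data[nz] == lab$data[nz]), 0.97)
})

test_that("transforms serialize to text + NIfTI and read back", {
  g <- default_phantom_grid(4)
  t <- make_subject_transform(13, grid = g)
  path <- file.path(tempdir(), "t_affine.txt")
  write_transform(t, path)
  rt <- read_transform(path)
  expect_equal(rt$affine, t$affine, tolerance = 1e-12)
  expect_equal(rt$displacement, t$displacement, tolerance = 1e-6)
  aff_only <- spatial_transform(t$affine)
  path2 <- file.path(tempdir(), "t2_affine.txt")
  write_transform(aff_only, path2)
  expect_null(read_transform(path2)$displacement)
})
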