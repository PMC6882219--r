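test_that("merging preserves counts, order and tags", {
  b <- subset_streamlines(tiny_bundle(), 1:6)
  groups <- lapply(1:5, function(j) {
    g <- b
    g$tags$subject <- sprintf("sub-%02d", j)
    g
  })
  merged <- merge_groups(groups)
  expect_equal(n_streamlines(merged), 30L)
  expect_equal(merged$tags$subject[7:12], rep("sub-02", 6))
  expect_equal(streamline_points(merged, 8), streamline_points(b, 2))
  one <- merge_groups(groups[1])
  expect_identical(one$coords, groups[[1]]$coords)
  expect_error(merge_groups(groups, affines = list(diag(4), 2 * diag(4))),
               "incompatible")
})

test_that("TDI matches the brute-force voxel walk exactly", {
  # small grids, few streamlines: independent R oracle
  set.seed(4)
  g <- volume_grid(c(18, 18, 18), {
    a <- diag(c(1.5, 1.5, 1.5, 1)); a[1:3, 4] <- c(0, 0, 0); a
  })
  mk <- function() {
    n <- sample(3:8, 1)
    start <- runif(3, 3, 10)
    step <- matrix(rnorm(3 * n, sd = 1.5), ncol = 3)
    pts <- apply(rbind(start, step), 2, cumsum)
    pts[] <- pmin(pmax(pts, 1), 24)
    streamline_set(pts, nrow(pts))
  }
  tracks <- concat_streamlines(replicate(40, mk(), simplify = FALSE))
  tdi <- compute_tdi(tracks, g)
  expect_identical(as.vector(tdi$data), as.vector(brute_tdi(tracks, g)))
})

test_that("TDI counts each streamline once and scales additively", {
  g <- volume_grid(c(10, 10, 10))
  # a streamline re-entering the same voxel twice still counts once
  loop <- streamline_set(rbind(c(2, 2, 2), c(4, 2, 2), c(4, 4, 2),
                               c(2, 4, 2), c(2, 2.2, 2)), 5L)
  t1 <- compute_tdi(loop, g)
  expect_true(all(t1$data %in% c(0L, 1L)))
  k <- 4
  rep_tracks <- concat_streamlines(replicate(k, loop, simplify = FALSE))
  tk <- compute_tdi(rep_tracks, g)
  expect_identical(tk$data, t1$data * as.integer(k))
  empty <- compute_tdi(streamline_set(), g)
  expect_true(all(empty$data == 0L))
})

test_that("label assignment follows subject support with the ORu tie rule", {
  g <- volume_grid(c(6, 6, 3))
  line <- function(subj) {
    s <- streamline_set(cbind(seq(0.6, 4.4, by = 0.4), 2, 1),
                        npts = length(seq(0.6, 4.4, by = 0.4)))
    s$tags$subject <- subj
    s
  }
  # equal support (2 subjects each) on the same voxels: tie goes to ORu
  div <- list(left_ORu = concat_streamlines(list(line("a"), line("b"))),
              left_ORl = concat_streamlines(list(line("a"), line("b"))))
  lab <- build_label_volume(div, g)
  expect_true(all(lab$data[lab$data != 0] == 1L))
  # larger ORl support wins
  div2 <- list(left_ORu = line("a"),
               left_ORl = concat_streamlines(list(line("a"), line("b"))))
  lab2 <- build_label_volume(div2, g)
  expect_true(all(lab2$data[lab2$data != 0] == 3L))
  # min_subject_support filters single-subject voxels
  lab3 <- build_label_volume(div2, g, min_subject_support = 2L)
  expect_true(all(lab3$data %in% c(0L, 3L)))
  expect_error(build_label_volume(list(foo = line("a")), g), "unknown division")
})

test_that("label volume equals the union of division footprints", {
  spec <- tiny_spec(n = 12)
  b <- make_phantom_bundle(spec, "left")
  b$tags$subject <- "s1"
  div <- split_divisions(b)
  lab <- build_label_volume(div, spec$grid)
  vox_u <- unlist(brute_streamline_voxels(div$left_ORu, spec$grid))
  vox_l <- unlist(brute_streamline_voxels(div$left_ORl, spec$grid))
  expect_setequal(which(lab$data != 0), union(vox_u, vox_l))
  expect_true(all(lab$data[setdiff(vox_u, vox_l)] == 1L))
  expect_true(all(lab$data[setdiff(vox_l, vox_u)] == 3L))
})

test_that("rigid registration recovers identity, shifts and rotations", {
  g <- volume_grid(c(40, 40, 20))
  m <- array(0L, g$shape)
  m[8:28, 10:20, 6:12] <- 1L   # anisotropic box
  m[10:14, 18:26, 8:10] <- 1L  # break symmetry
  mask <- label_volume(m, g)
  self <- rigid_register_masks(mask, mask)
  expect_lt(max(abs(oratlas:::rot_angles(self$affine[1:3, 1:3]))), 0.1)
  expect_lt(max(abs(self$affine[1:3, 4])), 0.1)
  shifted <- translate_labels(mask, c(5, 0, 0))
  t_sh <- rigid_register_masks(mask, shifted)
  expect_equal(unname(t_sh$affine[1:3, 4]), c(5, 0, 0), tolerance = 0.5)
  ctr <- colMeans(oratlas:::mask_points(mask))
  r <- oratlas:::rot_axis(3, 10)
  aff <- diag(4); aff[1:3, 1:3] <- r; aff[1:3, 4] <- ctr - r %*% ctr
  rotated <- resample_labels(mask, spatial_transform(solve(aff)), g)
  t_rot <- rigid_register_masks(mask, rotated)
  expect_equal(oratlas:::rot_angles(t_rot$affine[1:3, 1:3])[3], 10,
               tolerance = 1)
  expect_error(rigid_register_masks(
    label_volume(array(0L, g$shape), g), mask), "degenerate")
})

test_that("tract density thins toward the anterior extension of the loop", {
  spec <- tiny_spec(n = 100)
  b <- make_phantom_bundle(spec, "left")
  b$tags$subject <- "s1"
  tdi <- compute_tdi(b, spec$grid)
  yw <- grid_voxel_centers(spec$grid)[, 2]
  apex_y <- loop_apex_y(spec, "left")
  nz <- tdi$data > 0
  apex_slab <- nz & array(yw > apex_y - 4, spec$grid$shape)
  body_slab <- nz & array(yw > -50 & yw < -30, spec$grid$shape)
  expect_lt(mean(tdi$data[apex_slab]), mean(tdi$data[body_slab]))
})
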