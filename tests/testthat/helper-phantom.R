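# shared fixtures and independent oracles, built in code at test time

# small phantom for unit tests; the full default is exercised in acceptance
tiny_spec <- function(n = 40, ...) phantom_spec(n_streamlines = n, ...)

# cache expensive shared fixtures across test files
.fixture_env <- new.env(parent = emptyenv())
fixture <- function(name, builder) {
  if (is.null(.fixture_env[[name]])) .fixture_env[[name]] <- builder()
  .fixture_env[[name]]
}

tiny_bundle <- function() fixture("tiny_bundle", function()
  make_phantom_bundle(tiny_spec(), "left"))

tiny_field <- function() fixture("tiny_field", function()
  rasterize_orientation_field(tiny_bundle(), tiny_spec()$grid))

# independent brute-force voxel walk: supersample each segment at <= half
# the smallest voxel size, round to nearest voxel, unique per streamline
brute_streamline_voxels <- function(tracks, grid) {
  step <- min(voxel_sizes(grid)) / 2
  lapply(seq_len(n_streamlines(tracks)), function(i) {
    p <- streamline_points(tracks, i)
    pts <- list()
    for (q in seq_len(nrow(p) - 1)) {
      a <- p[q, ]; b <- p[q + 1, ]
      len <- sqrt(sum((b - a)^2))
      nsub <- max(1, ceiling(len / step))
      tt <- seq(0, 1, length.out = nsub + 1)
      pts[[q]] <- cbind(a[1] + tt * (b[1] - a[1]), a[2] + tt * (b[2] - a[2]),
                        a[3] + tt * (b[3] - a[3]))
    }
    vox <- round(world_to_voxel(grid, do.call(rbind, pts)))
    ok <- vox[, 1] >= 0 & vox[, 2] >= 0 & vox[, 3] >= 0 &
      vox[, 1] <= grid$shape[1] - 1 & vox[, 2] <= grid$shape[2] - 1 &
      vox[, 3] <= grid$shape[3] - 1
    sort(unique(1 + vox[ok, 1] + grid$shape[1] *
                  (vox[ok, 2] + grid$shape[2] * vox[ok, 3])))
  })
}

brute_tdi <- function(tracks, grid) {
  counts <- integer(prod(grid$shape))
  for (v in brute_streamline_voxels(tracks, grid))
    counts[v] <- counts[v] + 1L
  array(counts, grid$shape)
}

# exhaustive per-coronal-slice maxima scan over a slab
brute_max_density <- function(tdi, slab) {
  out <- integer(0)
  for (j in seq_len(tdi$grid$shape[2])) {
    vals <- tdi$data[, j, ]
    m <- slab[, j, ] & vals > 0
    if (!any(m)) next
    mx <- max(vals[m])
    idx <- which(m & vals == mx, arr.ind = TRUE)
    out <- c(out, as.integer(1 + (idx[, 1] - 1) + tdi$grid$shape[1] *
               ((j - 1) + tdi$grid$shape[2] * (idx[, 2] - 1))))
  }
  sort(out)
}

# straight-tube orientation field along +Y for tracker unit tests
straight_field <- function(ny = 120, qa_gap = NULL) {
  grid <- volume_grid(c(9, ny, 9), {
    a <- diag(c(1, 1, 1, 1)); a[1:3, 4] <- c(-4, 0, -4); a
  })
  dirs <- array(0, c(grid$shape, 3))
  dirs[, , , 2] <- 1
  qa <- array(1, grid$shape)
  if (!is.null(qa_gap)) qa[, qa_gap, ] <- 0  # gap must span >= 2 voxels
  orientation_field(dirs, qa, grid)
}

center_seed_mask <- function(grid) {
  m <- array(0L, grid$shape)
  c0 <- floor(grid$shape / 2) + 1L
  m[c0[1], c0[2], c0[3]] <- 1L
  label_volume(m, grid)
}

max_turn_deg <- function(tracks) {
  worst <- 0
  for (i in seq_len(n_streamlines(tracks))) {
    p <- streamline_points(tracks, i)
    if (nrow(p) < 3) next
    d <- diff(p)
    d <- d / sqrt(rowSums(d^2))
    dots <- rowSums(d[-1, , drop = FALSE] * d[-nrow(d), , drop = FALSE])
    worst <- max(worst, max(acos(pmin(1, pmax(-1, dots))) * 180 / pi))
  }
  worst
}
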