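#' Middle-third coronal slab of a region
#'
#' The middle third of the optic radiation (along the anterior-posterior
#' axis) has comparatively simple anatomy, so the correspondence validation
#' is restricted to it: with `[y_min, y_max]` the world-Y extent of the
#' side's nonzero voxels, the slab keeps voxels with
#' `Y in [y_min + L/3, y_min + 2L/3]`, `L = y_max - y_min`.
#'
#' @param region a [label_volume()] or [tdi_volume()].
#' @param side `"left"`, `"right"`, or `NULL` to use all nonzero voxels
#'   (for label volumes the side selects its two division labels; for TDI
#'   volumes the side selects voxels by the sign of world X).
#' @return logical array on the region grid marking the slab.
#' @export
middle_third_slab <- function(region, side = NULL) {
  sel <- region_side_mask(region, side)
  if (!any(sel)) stop("region is empty on the requested side")
  yw <- voxel_y_world(region$grid)
  ys <- yw[sel]
  lo <- min(ys) + diff(range(ys)) / 3
  hi <- min(ys) + 2 * diff(range(ys)) / 3
  array(sel & yw >= lo & yw <= hi, region$grid$shape)
}

# nonzero mask restricted to a side
region_side_mask <- function(region, side = NULL) {
  m <- as.vector(region$data) != 0
  if (!is.null(side)) {
    if (inherits(region, "label_volume")) {
      m <- as.vector(region$data) %in% side_labels(side)
    } else {
      xw <- grid_voxel_centers(region$grid)[, 1]
      m <- m & if (side == "left") xw < 0 else xw >= 0
    }
  }
  m
}

voxel_y_world <- function(grid) grid_voxel_centers(grid)[, 2]

#' Maximal tract-density voxels per coronal slice
#'
#' For every coronal slice (constant Y voxel index) intersecting the slab,
#' all voxels attaining that slice's maximum TDI value within the slab are
#' selected; the union over slices is returned. Ties are included. With
#' `per_slice = FALSE` the global top voxels of the slab are returned
#' instead.
#'
#' @param tdi a [tdi_volume()].
#' @param slab logical array from [middle_third_slab()].
#' @param per_slice per-coronal-slice maxima (default) or a single global
#'   maximum set.
#' @return integer vector of linear voxel indices (1-based, array order).
#' @export
max_density_voxels <- function(tdi, slab, per_slice = TRUE) {
  stopifnot(inherits(tdi, "tdi_volume"))
  v <- as.vector(tdi$data)
  sl <- as.vector(slab)
  if (!any(sl & v > 0)) stop("slab contains no positive tract density")
  idx <- which(sl & v > 0)
  if (!per_slice) return(idx[v[idx] == max(v[idx])])
  jj <- arrayInd(idx, tdi$grid$shape)[, 2]
  out <- integer(0)
  for (j in unique(jj)) {
    ii <- idx[jj == j]
    out <- c(out, ii[v[ii] == max(v[ii])])
  }
  sort(out)
}

#' Correspondence rate
#'
#' Fraction of maximal tract-density voxels that fall inside the side's
#' atlas-labeled region.
#'
#' @param max_voxels integer linear voxel indices from
#'   [max_density_voxels()]; must be nonempty.
#' @param labels a [label_volume()] on the same grid.
#' @param side `"left"` or `"right"`.
#' @return CR in `[0, 1]` (multiply by 100 for display).
#' @export
correspondence_rate <- function(max_voxels, labels, side) {
  if (!length(max_voxels)) stop("max_voxels is empty")
  mean(labels$data[max_voxels] %in% side_labels(side))
}

#' Shifted-CR profile and tolerable CR
#'
#' Emulates lateral registration error: the labels are translated along X by
#' each offset in `seq(-max_offset_mm, max_offset_mm, by = step_mm)` and the
#' CR recomputed against the fixed maximal-density voxels. The tolerable CR
#' per direction is the CR observed at the largest offset magnitude at which
#' the maximal-density voxels still touch the shifted labeled region (the
#' transition between intersection and non-intersection).
#'
#' @param tdi a [tdi_volume()].
#' @param labels a [label_volume()] on the same grid.
#' @param side `"left"` or `"right"`.
#' @param max_offset_mm largest offset magnitude probed.
#' @param step_mm offset increment (defaults to one voxel).
#' @param per_slice passed to [max_density_voxels()].
#' @return list with `profile` (data frame: `offset_mm`, `cr`,
#'   `intersects`), `tolerable_cr` (named: `left_dir`, `right_dir`; `NA`
#'   when no transition occurs within range) and `cr0` (the unshifted CR).
#' @export
shifted_cr_profile <- function(tdi, labels, side, max_offset_mm = 10,
                               step_mm = NULL, per_slice = TRUE) {
  if (is.null(step_mm)) step_mm <- voxel_sizes(labels$grid)[1]
  stopifnot(step_mm > 0)
  slab <- middle_third_slab(tdi, side)
  mv <- max_density_voxels(tdi, slab, per_slice)
  offsets <- seq(-max_offset_mm, max_offset_mm, by = step_mm)
  cr <- numeric(length(offsets))
  inter <- logical(length(offsets))
  for (i in seq_along(offsets)) {
    shifted <- translate_labels(labels, c(offsets[i], 0, 0))
    hit <- shifted$data[mv] %in% side_labels(side)
    cr[i] <- mean(hit)
    inter[i] <- any(hit)
  }
  tol <- c(left_dir = NA_real_, right_dir = NA_real_)
  for (dir in c(-1, 1)) {
    sel <- if (dir < 0) offsets < 0 else offsets > 0
    o <- offsets[sel][order(abs(offsets[sel]))]
    ci <- cr[sel][order(abs(offsets[sel]))]
    ii <- inter[sel][order(abs(offsets[sel]))]
    last <- if (any(ii)) max(which(ii)) else NA_integer_
    # a transition exists only if non-intersection is reached within range
    if (!is.na(last) && last < length(o))
      tol[if (dir < 0) "left_dir" else "right_dir"] <- ci[last]
  }
  if (all(is.na(tol)))
    warning("no intersection/non-intersection transition within the offset range; ",
            "tolerable CR undefined")
  list(profile = data.frame(offset_mm = offsets, cr = cr,
                            intersects = inter),
       tolerable_cr = tol,
       cr0 = cr[offsets == 0])
}

#' Percentile bootstrap CI for the mean CR
#'
#' Resamples the CR values with replacement `n_boot` times and returns the
#' percentile confidence interval of the resampled mean, plus the flag of
#' the representativeness check (observed mean inside its own bootstrap CI).
#'
#' @param cr_values numeric vector (at least 2 values, unless constant).
#' @param n_boot number of bootstrap resamples.
#' @param confidence confidence level.
#' @param rng_seed integer seed.
#' @return list `ci_low`, `ci_high`, `mean`, `mean_inside`.
#' @export
bootstrap_mean_ci <- function(cr_values, n_boot = 10000L, confidence = 0.95,
                              rng_seed = 1L) {
  stopifnot(length(cr_values) >= 2, n_boot >= 1)
  m <- mean(cr_values)
  if (max(cr_values) == min(cr_values))
    return(list(ci_low = m, ci_high = m, mean = m, mean_inside = TRUE))
  means <- with_seed(rng_seed, {
    idx <- matrix(sample.int(length(cr_values), length(cr_values) * n_boot,
                             replace = TRUE), nrow = n_boot)
    rowMeans(matrix(cr_values[idx], nrow = n_boot))
  })
  a <- (1 - confidence) / 2
  ci <- unname(stats::quantile(means, c(a, 1 - a)))
  list(ci_low = ci[1], ci_high = ci[2], mean = m,
       mean_inside = m >= ci[1] && m <= ci[2])
}

#' Surgical safety-zone check
#'
#' Dilates the side's labeled region by a Euclidean margin (world mm,
#' spherical structuring element over voxel centers) and checks that every
#' maximal tract-density voxel lies inside the dilated zone. This captures
#' the clinically relevant scenario of a low CR whose maximal-density voxels
#' nevertheless stay within a safe distance of the labeled area.
#'
#' @param labels a [label_volume()].
#' @param side `"left"` or `"right"`.
#' @param max_voxels integer linear indices of the maximal-density voxels.
#' @param margin_mm dilation radius in mm.
#' @return list `pass` (logical) and `margin_mask` (logical array).
#' @export
safety_zone_check <- function(labels, side, max_voxels, margin_mm = 5) {
  stopifnot(margin_mm >= 0)
  sh <- labels$grid$shape
  vs <- voxel_sizes(labels$grid)
  base <- array(as.vector(labels$data) %in% side_labels(side), sh)
  mask <- base
  reach <- floor(margin_mm / vs)
  for (dx in -reach[1]:reach[1])
    for (dy in -reach[2]:reach[2])
      for (dz in -reach[3]:reach[3]) {
        if (dx == 0 && dy == 0 && dz == 0) next
        if (sum((c(dx, dy, dz) * vs)^2) > margin_mm^2) next
        mask <- mask | shift_array(base, c(dx, dy, dz))
      }
  list(pass = all(mask[max_voxels]), margin_mask = mask)
}

# integer-voxel array shift with zero fill
shift_array <- function(a, d) {
  sh <- dim(a)
  out <- array(FALSE, sh)
  src <- dst <- vector("list", 3)
  for (ax in 1:3) {
    if (d[ax] >= 0) {
      dst[[ax]] <- (1 + d[ax]):sh[ax]
      src[[ax]] <- 1:(sh[ax] - d[ax])
    } else {
      dst[[ax]] <- 1:(sh[ax] + d[ax])
      src[[ax]] <- (1 - d[ax]):sh[ax]
    }
    if (abs(d[ax]) >= sh[ax]) return(out)
  }
  out[dst[[1]], dst[[2]], dst[[3]]] <- a[src[[1]], src[[2]], src[[3]]]
  out
}

#' Required sample size for a one-sample mean
#'
#' Smallest integer `n >= 2` such that a two-sided one-sample t-test of
#' `H0: mu = null_mean` at level `alpha` reaches the requested power when
#' the true mean is `alt_mean` and the standard deviation is `sd`. Power is
#' evaluated exactly with the noncentral t distribution.
#'
#' @param alt_mean tested mean under the alternative.
#' @param null_mean mean under the null hypothesis.
#' @param sd standard deviation (> 0).
#' @param alpha two-sided significance level.
#' @param power required power.
#' @param n_max search cap; unreachable power is an error.
#' @return integer sample size.
#' @export
required_sample_size <- function(alt_mean, null_mean, sd, alpha = 0.05,
                                 power = 0.90, n_max = 1e6) {
  stopifnot(sd > 0, alt_mean != null_mean, alpha > 0, alpha < 1,
            power > 0, power < 1)
  delta <- abs(alt_mean - null_mean)
  n <- 2
  while (n <= n_max) {
    if (t_test_power(delta, sd, n, alpha) >= power) return(as.integer(n))
    n <- n + 1
  }
  stop("requested power unreachable within n <= ", format(n_max))
}

# exact two-sided one-sample t-test power via the noncentral t distribution
t_test_power <- function(delta, sd, n, alpha) {
  df <- n - 1
  ncp <- delta / sd * sqrt(n)
  tcrit <- stats::qt(1 - alpha / 2, df)
  stats::pt(-tcrit, df, ncp) + 1 - stats::pt(tcrit, df, ncp)
}
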