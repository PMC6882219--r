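#' Merge per-subject streamline groups
#'
#' Concatenates groups of fibers tracked in a common space into one set,
#' preserving per-streamline subject and division tags. Groups that declare
#' grids must agree on the affine (mixed spaces are refused).
#'
#' @param groups list of [streamline_set()] objects.
#' @param affines optional list of 4x4 affines declared for each group; when
#'   given, all must match to `tol`.
#' @param tol affine agreement tolerance.
#' @return one merged [streamline_set()].
#' @export
merge_groups <- function(groups, affines = NULL, tol = 1e-6) {
  stopifnot(is.list(groups), length(groups) >= 1)
  if (!is.null(affines)) {
    ref <- affines[[1]]
    for (a in affines)
      if (max(abs(a - ref)) > tol)
        stop("groups declare incompatible affines; resample to one space first")
  }
  concat_streamlines(groups)
}

#' Compute a tract density image
#'
#' Each streamline increments every voxel it traverses by exactly one
#' (segments are supersampled at no more than half-voxel spacing; re-entering
#' a voxel does not count twice for the same streamline), so the voxel value
#' is the number of distinct tracts passing through the voxel.
#'
#' @param tracks a [streamline_set()].
#' @param grid target [volume_grid()]; points outside are clipped with a
#'   warning.
#' @return a [tdi_volume()].
#' @export
compute_tdi <- function(tracks, grid) {
  stopifnot(inherits(tracks, "streamline_set"), inherits(grid, "volume_grid"))
  counts <- integer(prod(grid$shape))
  if (n_streamlines(tracks)) {
    vox <- world_to_voxel(grid, tracks$coords)
    outside <- rowSums(vox < -0.5 | vox > matrix(grid$shape - 0.5,
                                                 nrow(vox), 3,
                                                 byrow = TRUE)) > 0
    if (any(outside))
      warning(sum(outside), " streamline point(s) outside the grid were clipped")
    vsets <- cpp_streamline_voxels(tracks$coords, tracks$npts, grid$shape,
                                   solve(grid$affine),
                                   min(voxel_sizes(grid)) / 2)
    tab <- tabulate(unlist(vsets, use.names = FALSE), nbins = length(counts))
    counts <- counts + tab
  }
  tdi_volume(array(counts, grid$shape), grid)
}

#' Build the four-region atlas label volume
#'
#' Voxels are assigned a division's label when traversed by at least
#' `min_subject_support` distinct subjects' streamlines of that division.
#' Where divisions overlap, the division with the larger subject support
#' wins; ties go to the upper division (the lower label code).
#'
#' @param division_tracks named list mapping division names (among
#'   `left_ORu`, `right_ORu`, `left_ORl`, `right_ORl`) to
#'   [streamline_set()]s whose tags carry the subject.
#' @param grid target [volume_grid()].
#' @param min_subject_support minimum number of distinct supporting subjects.
#' @return a [label_volume()] with the fixed 1-4 legend.
#' @export
build_label_volume <- function(division_tracks, grid,
                               min_subject_support = 1L) {
  legend <- atlas_legend()
  unknown <- setdiff(names(division_tracks), names(legend))
  if (length(unknown))
    stop("unknown division tag(s): ", paste(unknown, collapse = ", "))
  nvox <- prod(grid$shape)
  support <- matrix(0L, nvox, length(legend),
                    dimnames = list(NULL, names(legend)))
  for (div in names(division_tracks)) {
    trk <- division_tracks[[div]]
    if (!n_streamlines(trk)) next
    vsets <- cpp_streamline_voxels(trk$coords, trk$npts, grid$shape,
                                   solve(grid$affine),
                                   min(voxel_sizes(grid)) / 2)
    subj <- trk$tags$subject
    subj[is.na(subj)] <- "unknown"
    # distinct subjects per voxel: union of voxel sets within each subject
    for (s in unique(subj)) {
      vox_s <- unique(unlist(vsets[subj == s], use.names = FALSE))
      support[vox_s, div] <- support[vox_s, div] + 1L
    }
  }
  support[support < min_subject_support] <- 0L
  lab <- integer(nvox)
  any_support <- rowSums(support) > 0
  if (any(any_support)) {
    sub <- support[any_support, , drop = FALSE]
    # max support wins; ties resolve to the first (lowest label = ORu first)
    win <- max.col(sub, ties.method = "first")
    lab[any_support] <- legend[colnames(support)[win]]
  }
  label_volume(array(lab, grid$shape), grid)
}

#' Rigid registration of two label masks
#'
#' Estimates the rigid (rotation + translation) transform mapping the moving
#' mask onto the fixed mask: binary-mask centroids and principal inertia
#' axes are aligned first (trying the four proper-rotation axis-sign
#' combinations and keeping the best overlap), then the six rigid parameters
#' are refined by Nelder-Mead local search maximizing the Dice coefficient of
#' the nonzero voxels.
#'
#' @param moving,fixed [label_volume()] masks (nonzero voxels are used).
#' @param refine run the local Dice refinement.
#' @return a [spatial_transform()] mapping moving world coords to fixed
#'   world coords.
#' @export
rigid_register_masks <- function(moving, fixed, refine = TRUE) {
  pm <- mask_points(moving)
  pf <- mask_points(fixed)
  if (nrow(pm) <= 3 || nrow(pf) <= 3)
    stop("degenerate mask (<= 3 nonzero voxels); rigid registration needs larger masks")
  cm <- colMeans(pm)
  cf <- colMeans(pf)
  em <- eigen(stats::cov(pm))
  ef <- eigen(stats::cov(pf))
  if (any(em$values <= 0) ||
      any(abs(diff(em$values)) < 1e-3 * max(em$values)))
    stop("mask inertia is (near-)isotropic; principal axes are ambiguous")
  best <- NULL
  for (s1 in c(1, -1)) for (s2 in c(1, -1)) {
    vm <- em$vectors %*% diag(c(s1, s2, s1 * s2 * sign_det(em$vectors)))
    vf <- ef$vectors %*% diag(c(1, 1, sign_det(ef$vectors)))
    r <- vf %*% t(vm)
    if (det(r) < 0) next
    aff <- diag(4)
    aff[1:3, 1:3] <- r
    aff[1:3, 4] <- cf - r %*% cm
    d <- mask_dice(aff, moving, fixed)
    if (is.null(best) || d > best$dice) best <- list(aff = aff, dice = d)
  }
  aff <- best$aff
  if (refine) {
    th0 <- c(rot_angles(aff[1:3, 1:3]), aff[1:3, 4])
    obj <- function(th) -mask_dice(rigid_from_params(th), moving, fixed)
    opt <- stats::optim(th0, obj, method = "Nelder-Mead",
                        control = list(maxit = 200, reltol = 1e-4))
    if (-opt$value >= best$dice) aff <- rigid_from_params(opt$par)
  }
  spatial_transform(aff, provenance = "rigid mask registration")
}

sign_det <- function(v) if (det(v) < 0) -1 else 1

# XYZ Euler angles (degrees) of a rotation matrix, and back
rot_angles <- function(r) {
  ry <- asin(pmin(1, pmax(-1, -r[3, 1])))
  rx <- atan2(r[3, 2], r[3, 3])
  rz <- atan2(r[2, 1], r[1, 1])
  c(rx, ry, rz) * 180 / pi
}

rigid_from_params <- function(th) {
  r <- rot_axis(3, th[3]) %*% rot_axis(2, th[2]) %*% rot_axis(1, th[1])
  aff <- diag(4)
  aff[1:3, 1:3] <- r
  aff[1:3, 4] <- th[4:6]
  aff
}

mask_points <- function(vol) {
  idx <- which(vol$data != 0)
  if (!length(idx)) return(matrix(numeric(), 0, 3))
  voxel_to_world(vol$grid, arrayInd(idx, vol$grid$shape) - 1)
}

# Dice overlap of the moving mask pushed through aff against the fixed mask
mask_dice <- function(aff, moving, fixed) {
  pm <- mask_points(moving)
  q <- affine_to_points(aff, pm)
  sv <- round(world_to_voxel(fixed$grid, q))
  sh <- fixed$grid$shape
  inside <- sv[, 1] >= 0 & sv[, 2] >= 0 & sv[, 3] >= 0 &
    sv[, 1] <= sh[1] - 1 & sv[, 2] <= sh[2] - 1 & sv[, 3] <= sh[3] - 1
  hit <- unique(voxel_linear_index(sh, sv[inside, , drop = FALSE]))
  nfix <- sum(fixed$data != 0)
  2 * sum(fixed$data[hit] != 0) / (length(hit) + nfix)
}
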