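#' Spatial transform: affine plus optional dense displacement field
#'
#' Represents the world-to-world (mm) mappings used to carry the atlas into
#' individual space: `p' = A p + D(A p)`, i.e. an affine followed by a dense
#' displacement field sampled with trilinear interpolation at the
#' affine-transformed position. The displacement is zero outside its grid.
#'
#' @param affine invertible 4x4 matrix (world mm to world mm).
#' @param displacement optional 4-D array `c(grid$shape, 3)` of mm
#'   displacements on `grid`.
#' @param grid the [volume_grid()] carrying the displacement field (required
#'   when `displacement` is given).
#' @param provenance free-text provenance note.
#' @return an object of class `spatial_transform`.
#' @export
spatial_transform <- function(affine = diag(4), displacement = NULL,
                              grid = NULL, provenance = "") {
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("transform affine is not invertible")
  if (!is.null(displacement)) {
    stopifnot(inherits(grid, "volume_grid"))
    displacement <- array(as.numeric(displacement), c(grid$shape, 3L))
    if (!all(is.finite(displacement)))
      stop("displacement field must be finite everywhere")
  }
  structure(list(affine = affine, displacement = displacement, grid = grid,
                 provenance = provenance),
            class = "spatial_transform")
}

#' Identity transform
#' @return a pure-affine identity [spatial_transform()].
#' @export
identity_transform <- function() spatial_transform(diag(4))

#' @export
print.spatial_transform <- function(x, ...) {
  desc <- if (is.null(x$displacement)) "affine-only" else {
    m <- matrix(x$displacement, ncol = 3)
    sprintf("affine + displacement field (max |d| = %.2f mm)",
            max(sqrt(rowSums(m^2))))
  }
  cat("<spatial_transform>", desc, "\n")
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  invisible(x)
}

is_identity_affine <- function(a, tol = 1e-12) max(abs(a - diag(4))) < tol

#' Apply a transform to points
#'
#' @param t a [spatial_transform()].
#' @param points n x 3 matrix (or length-3 vector) of world mm points.
#' @param warn_outside warn when displaced points fall outside the field grid
#'   (the displacement is taken as zero there).
#' @return n x 3 matrix of transformed points.
#' @export
apply_to_points <- function(t, points, warn_outside = TRUE) {
  p <- rbind3(points)
  if (!all(is.finite(p))) stop("points must be finite")
  q <- cbind(p, 1) %*% t(t$affine)
  q <- q[, 1:3, drop = FALSE]
  if (!is.null(t$displacement)) {
    pv <- world_to_voxel(t$grid, q)
    inside <- pv[, 1] >= 0 & pv[, 2] >= 0 & pv[, 3] >= 0 &
      pv[, 1] <= t$grid$shape[1] - 1 & pv[, 2] <= t$grid$shape[2] - 1 &
      pv[, 3] <= t$grid$shape[3] - 1
    if (warn_outside && any(!inside))
      warning(sum(!inside), " point(s) outside the displacement grid; ",
              "zero displacement applied there")
    d <- cpp_trilinear_vec(as.numeric(t$displacement), t$grid$shape, 3L, pv)
    q <- q + d
  }
  q
}

#' Apply only the affine part
#' @keywords internal
affine_to_points <- function(affine, points) {
  p <- rbind3(points)
  h <- cbind(p, 1) %*% t(affine)
  h[, 1:3, drop = FALSE]
}

#' Compose two transforms
#'
#' `apply(compose(outer, inner), p)` equals `apply(outer, apply(inner, p))`;
#' exactly for affine-only pairs, and to interpolation accuracy when a
#' displacement field is involved (the composed residual is resampled onto
#' `grid`).
#'
#' @param outer,inner [spatial_transform()] objects.
#' @param grid grid on which to sample the composed displacement; defaults to
#'   the outer field grid, then the inner one.
#' @return a [spatial_transform()].
#' @export
compose_transforms <- function(outer, inner, grid = NULL) {
  if (is.null(outer$displacement) && is.null(inner$displacement))
    return(spatial_transform(outer$affine %*% inner$affine,
                             provenance = "composed affine"))
  if (is.null(grid)) grid <- if (!is.null(outer$grid)) outer$grid else inner$grid
  m <- outer$affine %*% inner$affine
  centers <- grid_voxel_centers(grid)         # w = M p sample positions
  p <- affine_to_points(solve(m), centers)    # p = M^-1 w
  target <- apply_to_points(outer,
                            apply_to_points(inner, p, warn_outside = FALSE),
                            warn_outside = FALSE)
  disp <- array(target - centers, c(grid$shape, 3L))
  spatial_transform(m, disp, grid, provenance = "composed")
}

#' Invert a transform
#'
#' The affine part is inverted exactly. A displacement field is inverted by
#' fixed-point iteration on the warp `w -> w + D(w)`: for each target
#' position the damped iteration `e <- -D(q + e)` runs until the largest
#' update falls below `tol_mm` (or `max_iter` sweeps), and the resulting inverse
#' warp is recombined with the inverse affine. The achieved round-trip
#' residual is stored in the result's provenance.
#'
#' @param t a [spatial_transform()] with positive Jacobian on its domain.
#' @param tol_mm fixed-point convergence tolerance in mm.
#' @param max_iter iteration cap; non-convergence is an error reporting the
#'   residual.
#' @param upsample refinement factor of the grid carrying the inverse field
#'   (the inverse of a trilinear warp is not trilinear; refinement keeps its
#'   representation error below the round-trip tolerance).
#' @return the inverse [spatial_transform()].
#' @export
invert_transform <- function(t, tol_mm = 0.001, max_iter = 200L,
                             upsample = 3L) {
  ainv <- solve(t$affine)
  if (is.null(t$displacement))
    return(spatial_transform(ainv, provenance = "inverse affine"))
  # the inverse warp of a trilinear field has kinks at the voxel faces of
  # its argument, and inverse queries can land marginally outside the
  # forward domain: store the inverse on a refined grid padded by a margin
  pad <- 4L # coarse voxels of margin on every face
  aff <- t$grid$affine
  aff[1:3, 4] <- aff[1:3, 4] - aff[1:3, 1:3] %*% rep(pad, 3)
  aff[1:3, 1:3] <- aff[1:3, 1:3] / upsample
  grid <- volume_grid(upsample * (t$grid$shape + 2L * pad - 1L) + 1L, aff)
  lin3_inv <- ainv[1:3, 1:3]
  # warp acts in the post-affine space; invert it on this grid
  q <- grid_voxel_centers(grid)
  e <- matrix(0, nrow(q), 3)
  dfield <- as.numeric(t$displacement)
  resid <- Inf
  for (it in seq_len(max_iter)) {
    pv <- world_to_voxel(t$grid, q + e)
    d <- cpp_trilinear_vec(dfield, t$grid$shape, 3L, pv)
    e_new <- -d
    resid <- max(sqrt(rowSums((e_new - e)^2)))
    # damped update: plain fixed-point iteration can oscillate where the
    # field is truncated at the grid boundary
    e <- e + 0.5 * (e_new - e)
    if (resid < tol_mm) break
  }
  if (resid >= tol_mm)
    stop(sprintf(
      "displacement inversion did not converge: residual %.4f mm after %d iterations",
      resid, max_iter))
  # inverse transform: S(w) = A^-1 (w + E(w)); in affine+field form with
  # B = A^-1 the field is F(B w) = A^-1_lin E(w), sampled at grid centers v:
  # w = B^-1 v = A v
  w <- affine_to_points(t$affine, grid_voxel_centers(grid))
  pv <- world_to_voxel(grid, w)
  # E at arbitrary w: interpolate the converged e (stored on grid centers q)
  efield <- array(e, c(grid$shape, 3L))
  ew <- cpp_trilinear_vec(as.numeric(efield), grid$shape, 3L, pv)
  fvec <- ew %*% t(lin3_inv)
  spatial_transform(ainv, array(fvec, c(grid$shape, 3L)), grid,
                    provenance = sprintf("inverse (fixed-point residual %.4g mm)",
                                         resid))
}

#' Resample a label volume through a transform (pull-back)
#'
#' Every target voxel center is mapped through `t` (which must map target
#' space to source space) and assigned the label of the nearest source voxel.
#' Only nearest-neighbor interpolation is used for labels, so no new label
#' values can appear.
#'
#' @param labels a [label_volume()] in source space.
#' @param t a [spatial_transform()] mapping target world coords to source
#'   world coords.
#' @param target_grid the output [volume_grid()].
#' @return a [label_volume()] on `target_grid`.
#' @export
resample_labels <- function(labels, t, target_grid) {
  stopifnot(inherits(labels, "label_volume"))
  centers <- grid_voxel_centers(target_grid)
  src <- apply_to_points(t, centers, warn_outside = FALSE)
  sv <- round(world_to_voxel(labels$grid, src))
  inside <- sv[, 1] >= 0 & sv[, 2] >= 0 & sv[, 3] >= 0 &
    sv[, 1] <= labels$grid$shape[1] - 1 &
    sv[, 2] <= labels$grid$shape[2] - 1 &
    sv[, 3] <= labels$grid$shape[3] - 1
  out <- integer(prod(target_grid$shape))
  lin <- 1L + sv[inside, 1] + labels$grid$shape[1] *
    (sv[inside, 2] + labels$grid$shape[2] * sv[inside, 3])
  out[inside] <- labels$data[lin]
  label_volume(array(out, target_grid$shape), target_grid)
}

#' Translate a label volume by a world-space offset
#'
#' Convenience wrapper used by the shift-tolerance procedure: resamples the
#' labels onto their own grid after translating them by `offset_mm`.
#'
#' @param labels a [label_volume()].
#' @param offset_mm length-3 world offset in mm (the labels move by +offset).
#' @return translated [label_volume()] on the same grid.
#' @export
translate_labels <- function(labels, offset_mm) {
  stopifnot(length(offset_mm) == 3L)
  a <- diag(4)
  a[1:3, 4] <- -as.numeric(offset_mm) # pull-back: target -> source
  resample_labels(labels, spatial_transform(a), labels$grid)
}

# --- serialization -----------------------------------------------------------

#' Write / read a transform
#'
#' The affine goes to a 4-line plain-text file (4x4 matrix, whitespace
#' separated); a displacement field, when present, to a 4-D NIfTI (last
#' dimension 3, mm units, RAS+) alongside it with suffix `_field.nii.gz`.
#'
#' @param t a [spatial_transform()].
#' @param path path of the affine text file; the field path is derived from
#'   it.
#' @return `write_transform` returns the written path(s) invisibly;
#'   `read_transform` returns a [spatial_transform()].
#' @export
write_transform <- function(t, path) {
  write.table(t$affine, path, row.names = FALSE, col.names = FALSE)
  paths <- path
  if (!is.null(t$displacement)) {
    fpath <- sub("(\\.txt)?$", "_field.nii.gz", path)
    write_displacement_nifti(t$displacement, t$grid, fpath)
    paths <- c(paths, fpath)
  }
  invisible(paths)
}

#' @rdname write_transform
#' @export
read_transform <- function(path) {
  aff <- as.matrix(read.table(path))
  dimnames(aff) <- NULL
  fpath <- sub("(\\.txt)?$", "_field.nii.gz", path)
  if (file.exists(fpath)) {
    fld <- read_displacement_nifti(fpath)
    spatial_transform(aff, fld$field, fld$grid, provenance = path)
  } else {
    spatial_transform(aff, provenance = path)
  }
}
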