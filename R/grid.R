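#' Volume grid: shape plus voxel-to-world affine
#'
#' A `volume_grid` couples an integer array shape with a 4x4 affine mapping
#' 0-based voxel indices to world coordinates in mm. The convention used
#' throughout the package is RAS+ world axes (+X right, +Y anterior, +Z
#' superior) with voxel centers located exactly at integer indices.
#'
#' @param shape integer vector of length 3, voxels per axis (all positive).
#' @param affine 4x4 numeric matrix, voxel index (0-based) to world mm.
#' @return an object of class `volume_grid` with elements `shape` and
#'   `affine`.
#' @examples
#' g <- volume_grid(c(10, 12, 8), affine = diag(c(1.5, 1.5, 1.5, 1)))
#' voxel_to_world(g, rbind(c(0, 0, 0), c(9, 11, 7)))
#' @export
volume_grid <- function(shape, affine = diag(4)) {
  shape <- as.integer(shape)
  stopifnot(length(shape) == 3L, all(shape >= 1L))
  affine <- as.matrix(affine)
  stopifnot(identical(dim(affine), c(4L, 4L)))
  if (abs(det(affine)) < .Machine$double.eps * 100)
    stop("grid affine is not invertible")
  vs <- sqrt(colSums(affine[1:3, 1:3]^2))
  if (any(vs <= 0)) stop("grid voxel sizes must be strictly positive")
  structure(list(shape = shape, affine = affine), class = "volume_grid")
}

#' @export
print.volume_grid <- function(x, ...) {
  cat(sprintf("<volume_grid> %d x %d x %d voxels, voxel size %s mm\n",
              x$shape[1], x$shape[2], x$shape[3],
              paste(signif(voxel_sizes(x), 4), collapse = " x ")))
  invisible(x)
}

#' Voxel edge lengths of a grid in mm
#' @param grid a [volume_grid()].
#' @return numeric length-3 vector of voxel sizes.
#' @export
voxel_sizes <- function(grid) {
  sqrt(colSums(grid$affine[1:3, 1:3]^2))
}

#' Convert voxel indices to world coordinates
#'
#' @param grid a [volume_grid()].
#' @param vox n x 3 matrix (or length-3 vector) of 0-based voxel coordinates;
#'   fractional values are allowed.
#' @return n x 3 matrix of world mm coordinates.
#' @export
voxel_to_world <- function(grid, vox) {
  vox <- rbind3(vox)
  h <- cbind(vox, 1) %*% t(grid$affine)
  h[, 1:3, drop = FALSE]
}

#' Convert world coordinates to (fractional) voxel indices
#' @inheritParams voxel_to_world
#' @param world n x 3 matrix (or length-3 vector) of world mm coordinates.
#' @return n x 3 matrix of 0-based voxel coordinates.
#' @export
world_to_voxel <- function(grid, world) {
  world <- rbind3(world)
  h <- cbind(world, 1) %*% t(solve(grid$affine))
  h[, 1:3, drop = FALSE]
}

# coerce a length-3 vector or n x 3 matrix to matrix form
rbind3 <- function(x) {
  if (is.null(dim(x))) {
    stopifnot(length(x) == 3L)
    x <- matrix(as.numeric(x), 1L, 3L)
  }
  storage.mode(x) <- "double"
  stopifnot(ncol(x) == 3L)
  x
}

#' Default grid for the bundled phantom geometry
#'
#' Covers both hemispheres of the synthetic optic-radiation phantom with a
#' margin, at an isotropic voxel size (1.5 mm by default, matching
#' high-angular-resolution diffusion acquisitions).
#'
#' @param voxel_mm isotropic voxel size in mm (2 mm by default, a common
#'   diffusion acquisition resolution).
#' @return a [volume_grid()] spanning X in [-54, 54], Y in [-86, 38],
#'   Z in [-36, 36] mm.
#' @export
default_phantom_grid <- function(voxel_mm = 2) {
  lo <- c(-54, -86, -36)
  hi <- c(54, 38, 36)
  shape <- floor((hi - lo) / voxel_mm) + 1L
  aff <- diag(c(rep(voxel_mm, 3), 1))
  aff[1:3, 4] <- lo
  volume_grid(shape, aff)
}

# --- volumes -----------------------------------------------------------------

new_volume <- function(data, grid, class) {
  stopifnot(inherits(grid, "volume_grid"))
  data <- array(data, dim = grid$shape)
  structure(list(grid = grid, data = data), class = c(class, "ora_volume"))
}

#' Integer label volume for atlas regions
#'
#' Labels follow the fixed atlas legend: 0 = background, 1 = left upper
#' division (ORu), 2 = right ORu, 3 = left lower division (ORl), 4 = right
#' ORl.
#'
#' @param data integer array matching `grid$shape` with values in 0..4.
#' @param grid a [volume_grid()].
#' @return a `label_volume` object (list with `grid` and integer array
#'   `data`).
#' @export
label_volume <- function(data, grid) {
  v <- new_volume(as.integer(data), grid, "label_volume")
  bad <- setdiff(unique(as.vector(v$data)), 0:4)
  if (length(bad))
    stop("label volume contains values outside 0..4: ",
         paste(bad, collapse = ", "))
  v
}

#' Tract density image (TDI)
#'
#' Per-voxel count of distinct streamlines traversing the voxel.
#'
#' @param data non-negative integer array matching `grid$shape`.
#' @param grid a [volume_grid()].
#' @return a `tdi_volume` object.
#' @export
tdi_volume <- function(data, grid) {
  v <- new_volume(as.integer(data), grid, "tdi_volume")
  if (any(v$data < 0)) stop("TDI counts must be non-negative")
  v
}

#' Scalar volume (QA maps, synthetic T1-like images)
#' @param data numeric array matching `grid$shape`.
#' @param grid a [volume_grid()].
#' @return a `scalar_volume` object.
#' @export
scalar_volume <- function(data, grid) {
  new_volume(as.numeric(data), grid, "scalar_volume")
}

#' @export
print.ora_volume <- function(x, ...) {
  cat(sprintf("<%s> %s voxels, %d nonzero\n", class(x)[1],
              paste(x$grid$shape, collapse = " x "),
              sum(x$data != 0)))
  invisible(x)
}

#' World coordinates of all voxel centers
#' @param grid a [volume_grid()].
#' @return (prod(shape)) x 3 matrix in array (column-major) order.
#' @export
grid_voxel_centers <- function(grid) {
  idx <- arrayInd(seq_len(prod(grid$shape)), grid$shape) - 1
  voxel_to_world(grid, idx)
}

#' The atlas label legend
#'
#' @return named integer vector mapping division names (`left_ORu`,
#'   `right_ORu`, `left_ORl`, `right_ORl`) to label codes 1..4.
#' @export
atlas_legend <- function() {
  c(left_ORu = 1L, right_ORu = 2L, left_ORl = 3L, right_ORl = 4L)
}

#' Label codes belonging to one side
#' @param side `"left"` or `"right"`.
#' @return integer vector of the side's label codes.
#' @export
side_labels <- function(side = c("left", "right")) {
  side <- match.arg(side)
  lg <- atlas_legend()
  unname(lg[startsWith(names(lg), side)])
}
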