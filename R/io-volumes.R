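#' Read and write volumes as NIfTI-1
#'
#' Volumes round-trip through NIfTI with exact data values and the affine
#' preserved to single precision; label and TDI volumes are written with an
#' integer datatype.
#'
#' @param vol a [label_volume()], [tdi_volume()] or [scalar_volume()].
#' @param path file path (`.nii` or `.nii.gz`).
#' @return `write_volume` returns `path` invisibly; the readers return the
#'   corresponding volume object.
#' @export
write_volume <- function(vol, path) {
  stopifnot(inherits(vol, "ora_volume"))
  dtype <- if (inherits(vol, "scalar_volume")) "double" else "int32"
  img <- RNifti::asNifti(vol$data)
  img <- RNifti::`sform<-`(img, structure(vol$grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = dtype)
  invisible(path)
}

read_nifti_raw <- function(path) {
  if (!file.exists(path)) stop("no such NIfTI file: ", path)
  img <- RNifti::readNifti(path)
  aff <- unclass(RNifti::xform(img))
  attr(aff, "imagedim") <- NULL
  aff <- matrix(as.numeric(aff), 4, 4)
  if (abs(det(aff)) < 1e-12)
    stop("non-invertible affine in ", path)
  dims <- dim(img)
  list(data = as.array(img), affine = aff, dims = dims)
}

#' @rdname write_volume
#' @export
read_scalar_volume <- function(path) {
  r <- read_nifti_raw(path)
  stopifnot(length(r$dims) == 3)
  scalar_volume(r$data, volume_grid(r$dims, r$affine))
}

#' @rdname write_volume
#' @export
read_label_volume <- function(path) {
  r <- read_nifti_raw(path)
  stopifnot(length(r$dims) == 3)
  if (any(r$data != round(r$data)))
    stop("cannot read ", path, " as labels: non-integer data (storage mode ",
         storage.mode(r$data), ")")
  label_volume(array(as.integer(r$data), r$dims),
               volume_grid(r$dims, r$affine))
}

#' @rdname write_volume
#' @export
read_tdi_volume <- function(path) {
  r <- read_nifti_raw(path)
  stopifnot(length(r$dims) == 3)
  if (any(r$data != round(r$data)))
    stop("cannot read ", path, " as a TDI: non-integer data")
  tdi_volume(array(as.integer(r$data), r$dims), volume_grid(r$dims, r$affine))
}

#' Read and write orientation fields
#'
#' The direction field goes to a 4-D NIfTI (last dimension 3) and the QA map
#' to a 3-D NIfTI sharing the same affine.
#'
#' @param field an `orientation_field`.
#' @param dir_path,qa_path NIfTI paths for the direction and QA components.
#' @return `write_orientation_field` returns the paths invisibly;
#'   `read_orientation_field` an `orientation_field`.
#' @export
write_orientation_field <- function(field, dir_path, qa_path) {
  img <- RNifti::asNifti(field$dir)
  img <- RNifti::`sform<-`(img, structure(field$grid$affine, code = 2L))
  RNifti::writeNifti(img, dir_path, datatype = "double")
  write_volume(scalar_volume(field$qa, field$grid), qa_path)
  invisible(c(dir_path, qa_path))
}

#' @rdname write_orientation_field
#' @export
read_orientation_field <- function(dir_path, qa_path) {
  r <- read_nifti_raw(dir_path)
  stopifnot(length(r$dims) == 4, r$dims[4] == 3)
  qa <- read_scalar_volume(qa_path)
  grid <- volume_grid(r$dims[1:3], r$affine)
  orientation_field(r$data, qa$data, grid)
}

# displacement fields share the 4-D layout
write_displacement_nifti <- function(disp, grid, path) {
  img <- RNifti::asNifti(disp)
  img <- RNifti::`sform<-`(img, structure(grid$affine, code = 2L))
  RNifti::writeNifti(img, path, datatype = "double")
  invisible(path)
}

read_displacement_nifti <- function(path) {
  r <- read_nifti_raw(path)
  stopifnot(length(r$dims) == 4, r$dims[4] == 3)
  list(field = r$data, grid = volume_grid(r$dims[1:3], r$affine))
}
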