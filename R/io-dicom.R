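#' DICOM export specification
#'
#' Describes a navigation/robot-compatible export of a labeled anatomical
#' volume: the scalar source volume is rescaled to the 12-bit range and the
#' atlas-labeled voxels are burned into the pixel data at a fixed intensity,
#' one secondary-capture-style DICOM file per slice. Series identifiers
#' (UIDs) are generated deterministically from a seed so re-exports are
#' byte-identical.
#'
#' @param volume a [scalar_volume()] (the T1-like anatomical image).
#' @param overlay a [label_volume()] on the same grid.
#' @param burn_in intensity written into labeled voxels (within 0..4095).
#' @param uid_seed integer seed for the deterministic UIDs.
#' @param patient_id,patient_name identifier strings for the series.
#' @param slice_axis voxel axis sliced into files (3 = axial for an RAS
#'   grid).
#' @return a `dicom_export_spec` object.
#' @export
dicom_export_spec <- function(volume, overlay, burn_in = 4095,
                              uid_seed = 1L, patient_id = "PHANTOM",
                              patient_name = "Phantom^OR",
                              slice_axis = 3L) {
  stopifnot(inherits(volume, "scalar_volume"),
            inherits(overlay, "label_volume"))
  if (!identical(volume$grid$shape, overlay$grid$shape) ||
      max(abs(volume$grid$affine - overlay$grid$affine)) > 1e-6)
    stop("volume and overlay must share one grid")
  stopifnot(burn_in >= 0, burn_in <= 4095, slice_axis %in% 1:3)
  structure(list(volume = volume, overlay = overlay, burn_in = burn_in,
                 uid_seed = as.integer(uid_seed), patient_id = patient_id,
                 patient_name = patient_name,
                 slice_axis = as.integer(slice_axis)),
            class = "dicom_export_spec")
}

# deterministic DICOM UID under the 2.25 (UUID-derived) root
make_uid <- function(rng, n_digits = 30) {
  paste0("2.25.", paste(rng(n_digits), collapse = ""))
}

#' Export a labeled volume as a DICOM series
#'
#' Writes one explicit-VR little-endian DICOM file per slice along the
#' chosen axis. Pixel values are the source volume rescaled to 0..4095 with
#' labeled voxels replaced by the burn-in intensity; geometry tags (pixel
#' spacing, image position/orientation in the DICOM LPS frame, slice
#' thickness) are derived from the grid affine so that world coordinates are
#' recoverable from the files.
#'
#' @param spec a [dicom_export_spec()].
#' @param out_dir output directory (created if missing).
#' @return character vector of the written file paths, in instance order.
#' @export
export_dicom_series <- function(spec, out_dir) {
  stopifnot(inherits(spec, "dicom_export_spec"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  vol <- spec$volume$data
  lab <- spec$overlay$data
  aff <- spec$volume$grid$affine
  # permute so the slice axis is third
  perm <- c(setdiff(1:3, spec$slice_axis), spec$slice_axis)
  if (!identical(perm, 1:3)) {
    vol <- aperm(vol, perm)
    lab <- aperm(lab, perm)
    aff <- aff[, c(perm, 4)]
  }
  rng <- with_seed(spec$uid_seed, {
    digits <- sample(0:9, 4096, replace = TRUE)
    pos <- 0L
    function(n) {
      pos <<- pos + n
      digits[(pos - n + 1):pos]
    }
  })
  study_uid <- make_uid(rng)
  series_uid <- make_uid(rng)
  frame_uid <- make_uid(rng)
  rangev <- range(vol)
  scale <- if (diff(rangev) > 0) 4095 / diff(rangev) else 0
  pix <- round((vol - rangev[1]) * scale)
  pix[lab != 0] <- spec$burn_in
  sh <- dim(vol)
  lps <- diag(c(-1, -1, 1))
  col_i <- aff[1:3, 1]
  col_j <- aff[1:3, 2]
  sp_i <- vnorm(col_i)
  sp_j <- vnorm(col_j)
  iop <- c(lps %*% (col_i / sp_i), lps %*% (col_j / sp_j))
  thick <- vnorm(aff[1:3, 3])
  paths <- character(sh[3])
  for (k in seq_len(sh[3])) {
    ipp <- as.numeric(lps %*% (aff[1:3, ] %*% c(0, 0, k - 1, 1)))
    sop_uid <- make_uid(rng)
    slice <- matrix(as.integer(pix[, , k]), sh[1], sh[2])
    paths[k] <- file.path(out_dir, sprintf("slice-%04d.dcm", k))
    write_dicom_slice(paths[k], slice,
                      rows = sh[2], cols = sh[1],
                      ipp = ipp, iop = iop,
                      spacing = c(sp_j, sp_i), thickness = thick,
                      instance = k, sop_uid = sop_uid,
                      study_uid = study_uid, series_uid = series_uid,
                      frame_uid = frame_uid,
                      patient_id = spec$patient_id,
                      patient_name = spec$patient_name)
  }
  paths
}

# --- minimal explicit-VR little-endian writer --------------------------------

dcm_string <- function(group, element, vr, value, pad = as.raw(0x20)) {
  v <- charToRaw(value)
  if (length(v) %% 2) v <- c(v, pad)
  c(writeBin(c(group, element), raw(), size = 2, endian = "little"),
    charToRaw(vr),
    writeBin(length(v), raw(), size = 2, endian = "little"),
    v)
}

dcm_us <- function(group, element, value) {
  c(writeBin(c(group, element), raw(), size = 2, endian = "little"),
    charToRaw("US"),
    writeBin(2L, raw(), size = 2, endian = "little"),
    writeBin(as.integer(value), raw(), size = 2, endian = "little"))
}

dcm_long <- function(group, element, vr, payload) {
  # VRs with the 4-byte length form (OB, OW, UT, UN, SQ)
  c(writeBin(c(group, element), raw(), size = 2, endian = "little"),
    charToRaw(vr), as.raw(c(0, 0)),
    writeBin(length(payload), raw(), size = 4, endian = "little"),
    payload)
}

dcm_ds <- function(group, element, values) {
  dcm_string(group, element, "DS",
             paste(formatC(values, format = "fg", digits = 10),
                   collapse = "\\"))
}

write_dicom_slice <- function(path, slice, rows, cols, ipp, iop, spacing,
                              thickness, instance, sop_uid, study_uid,
                              series_uid, frame_uid, patient_id,
                              patient_name) {
  sc_class <- "1.2.840.10008.5.1.4.1.1.7" # secondary capture storage
  ts <- "1.2.840.10008.1.2.1"             # explicit VR little endian
  meta <- c(
    dcm_long(0x0002L, 0x0001L, "OB", as.raw(c(0, 1))),
    dcm_string(0x0002L, 0x0002L, "UI", sc_class, pad = as.raw(0)),
    dcm_string(0x0002L, 0x0003L, "UI", sop_uid, pad = as.raw(0)),
    dcm_string(0x0002L, 0x0010L, "UI", ts, pad = as.raw(0)),
    dcm_string(0x0002L, 0x0012L, "UI", "2.25.8631480462953", pad = as.raw(0)))
  meta_len <- c(
    writeBin(c(0x0002L, 0x0000L), raw(), size = 2, endian = "little"),
    charToRaw("UL"),
    writeBin(4L, raw(), size = 2, endian = "little"),
    writeBin(length(meta), raw(), size = 4, endian = "little"))
  pixel <- writeBin(as.integer(as.vector(slice)), raw(), size = 2,
                    endian = "little")
  body <- c(
    dcm_string(0x0008L, 0x0016L, "UI", sc_class, pad = as.raw(0)),
    dcm_string(0x0008L, 0x0018L, "UI", sop_uid, pad = as.raw(0)),
    dcm_string(0x0008L, 0x0020L, "DA", "20200101"),
    dcm_string(0x0008L, 0x0030L, "TM", "120000"),
    dcm_string(0x0008L, 0x0060L, "CS", "OT"),
    dcm_string(0x0010L, 0x0010L, "PN", patient_name),
    dcm_string(0x0010L, 0x0020L, "LO", patient_id),
    dcm_string(0x0018L, 0x0050L, "DS",
               formatC(thickness, format = "fg", digits = 10)),
    dcm_string(0x0020L, 0x000DL, "UI", study_uid, pad = as.raw(0)),
    dcm_string(0x0020L, 0x000EL, "UI", series_uid, pad = as.raw(0)),
    dcm_string(0x0020L, 0x0011L, "IS", "1"),
    dcm_string(0x0020L, 0x0013L, "IS", as.character(instance)),
    dcm_ds(0x0020L, 0x0032L, ipp),
    dcm_ds(0x0020L, 0x0037L, iop),
    dcm_string(0x0020L, 0x0052L, "UI", frame_uid, pad = as.raw(0)),
    dcm_us(0x0028L, 0x0002L, 1L),
    dcm_string(0x0028L, 0x0004L, "CS", "MONOCHROME2"),
    dcm_us(0x0028L, 0x0010L, rows),
    dcm_us(0x0028L, 0x0011L, cols),
    dcm_ds(0x0028L, 0x0030L, spacing),
    dcm_us(0x0028L, 0x0100L, 16L),
    dcm_us(0x0028L, 0x0101L, 12L),
    dcm_us(0x0028L, 0x0102L, 11L),
    dcm_us(0x0028L, 0x0103L, 0L),
    dcm_long(0x7FE0L, 0x0010L, "OW", pixel))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(raw(128), con)
  writeChar("DICM", con, eos = NULL)
  writeBin(c(meta_len, meta, body), con)
  invisible(path)
}

#' Read back geometry and pixels from an exported DICOM slice
#'
#' A minimal explicit-VR little-endian parser covering the tags this
#' package writes; intended for verification of exported series (geometry
#' consistency, burn-in, determinism), not as a general DICOM reader.
#'
#' @param path a DICOM file written by [export_dicom_series()].
#' @return list with `rows`, `cols`, `ipp`, `iop`, `spacing`, `thickness`,
#'   `instance`, `sop_uid`, `series_uid`, `pixels` (cols x rows integer
#'   matrix).
#' @export
read_dicom_slice <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  if (rawToChar(raw[129:132]) != "DICM") stop(path, " is not DICOM")
  pos <- 133L
  out <- list()
  n <- length(raw)
  long_vrs <- c("OB", "OW", "UT", "UN", "SQ")
  while (pos + 8 <= n + 1) {
    grp <- readBin(raw[pos:(pos + 1)], "integer", size = 2, endian = "little",
                   signed = FALSE)
    ele <- readBin(raw[(pos + 2):(pos + 3)], "integer", size = 2,
                   endian = "little", signed = FALSE)
    vr <- rawToChar(raw[(pos + 4):(pos + 5)])
    if (vr %in% long_vrs) {
      len <- readBin(raw[(pos + 8):(pos + 11)], "integer", size = 4,
                     endian = "little")
      data_at <- pos + 12L
    } else {
      len <- readBin(raw[(pos + 6):(pos + 7)], "integer", size = 2,
                     endian = "little", signed = FALSE)
      data_at <- pos + 8L
    }
    val <- if (len > 0) raw[data_at:(data_at + len - 1L)] else raw(0)
    key <- sprintf("%04x,%04x", grp, ele)
    txt <- function() {
      v <- val[val != as.raw(0)] # strip UI nul padding before decoding
      sub(" +$", "", rawToChar(v))
    }
    if (key == "0028,0010") out$rows <- readBin(val, "integer", size = 2,
                                                endian = "little")
    if (key == "0028,0011") out$cols <- readBin(val, "integer", size = 2,
                                                endian = "little")
    if (key == "0020,0032") out$ipp <- as.numeric(strsplit(txt(), "\\\\")[[1]])
    if (key == "0020,0037") out$iop <- as.numeric(strsplit(txt(), "\\\\")[[1]])
    if (key == "0028,0030") out$spacing <-
        as.numeric(strsplit(txt(), "\\\\")[[1]])
    if (key == "0018,0050") out$thickness <- as.numeric(txt())
    if (key == "0020,0013") out$instance <- as.integer(txt())
    if (key == "0008,0018") out$sop_uid <- txt()
    if (key == "0020,000e") out$series_uid <- txt()
    if (key == "7fe0,0010")
      out$pixels_raw <- val
    pos <- data_at + len
  }
  if (!is.null(out$pixels_raw)) {
    v <- readBin(out$pixels_raw, "integer", size = 2, endian = "little",
                 signed = FALSE, n = length(out$pixels_raw) / 2)
    out$pixels <- matrix(v, out$cols, out$rows)
    out$pixels_raw <- NULL
  }
  out
}
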