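#' Deterministic tracking parameters
#'
#' Defaults follow the deterministic (streamlined) algorithm settings used
#' for optic-radiation tracking on QA-based orientation fields: angular
#' threshold 90 degrees, step size 0.5 mm, direction smoothing 0.8, length
#' window 30-300 mm, and a budget of 50,000 seeds. The QA termination
#' threshold has no universal value (on real data it is tuned on the ODF
#' map); it is required here, or can be estimated with
#' [suggest_qa_threshold()].
#'
#' @param qa_threshold tracking stops where interpolated QA falls below this
#'   value (required, `>= 0`).
#' @param angular_threshold_deg maximum turn per step, degrees.
#' @param step_mm step size in mm.
#' @param smoothing weight of the previous direction in the direction
#'   update, in `[0, 1]`: `d_new = normalize(s * d_prev + (1-s) * field)`.
#' @param min_length_mm,max_length_mm retained streamline length window, mm.
#' @param seed_count number of seeds processed (seeds, not retained
#'   streamlines).
#' @param rng_seed integer seed for the sub-voxel seed positions.
#' @return a `tracking_params` object.
#' @export
tracking_params <- function(qa_threshold,
                            angular_threshold_deg = 90,
                            step_mm = 0.5,
                            smoothing = 0.8,
                            min_length_mm = 30,
                            max_length_mm = 300,
                            seed_count = 50000L,
                            rng_seed = 1L) {
  stopifnot(qa_threshold >= 0, smoothing >= 0, smoothing <= 1,
            step_mm > 0, min_length_mm > 0,
            min_length_mm <= max_length_mm, seed_count >= 1)
  structure(list(qa_threshold = qa_threshold,
                 angular_threshold_deg = angular_threshold_deg,
                 step_mm = step_mm, smoothing = smoothing,
                 min_length_mm = min_length_mm,
                 max_length_mm = max_length_mm,
                 seed_count = as.integer(seed_count),
                 rng_seed = as.integer(rng_seed)),
            class = "tracking_params")
}

#' Heuristic QA threshold from a tissue mask
#'
#' On real data the QA threshold is chosen by inspecting where the
#' orientation signal lies relative to brain tissue. This automatic stand-in
#' picks the smallest threshold such that at least `frac` of the
#' suprathreshold QA mass lies inside the supplied tissue mask.
#'
#' @param field an `orientation_field`.
#' @param tissue_mask logical/0-1 array on the same grid.
#' @param frac required inside-mask fraction of suprathreshold QA mass.
#' @return numeric threshold.
#' @export
suggest_qa_threshold <- function(field, tissue_mask, frac = 0.99) {
  qa <- as.vector(field$qa)
  inside <- as.vector(tissue_mask) > 0
  cand <- sort(unique(c(0, qa[qa > 0])))
  for (thr in cand) {
    sel <- qa >= thr & qa > 0
    tot <- sum(qa[sel])
    if (tot == 0) break
    if (sum(qa[sel & inside]) / tot >= frac) return(thr)
  }
  max(qa)
}

#' Deterministic streamline tracking
#'
#' Seeds are drawn uniformly over the seed-mask volume (voxel chosen with
#' replacement, sub-voxel position uniform within the voxel). From each seed
#' the tracker runs bidirectionally: the direction field is interpolated
#' trilinearly with per-corner antipodal sign alignment, blended with the
#' previous direction by the smoothing weight, and the position advanced by
#' the step size. A branch terminates when interpolated QA falls below the
#' threshold, the per-step turn exceeds the angular threshold, the position
#' leaves the grid, or the total length would exceed the maximum. Streamlines
#' shorter than the minimum length are discarded (seeds are still counted).
#'
#' @param field an `orientation_field`.
#' @param params a [tracking_params()].
#' @param seed_mask 0/1 [label_volume()] (or logical array on the field
#'   grid) of seed voxels.
#' @param side,subject optional tags stored on the resulting streamlines.
#' @param verbose log seed/retained counts and mean length.
#' @return a [streamline_set()].
#' @export
track_streamlines <- function(field, params, seed_mask,
                              side = NA_character_,
                              subject = NA_character_, verbose = FALSE) {
  stopifnot(inherits(field, "orientation_field"),
            inherits(params, "tracking_params"))
  mask <- if (inherits(seed_mask, "ora_volume")) seed_mask$data else seed_mask
  mask_idx <- which(as.vector(mask) > 0)
  if (!length(mask_idx)) stop("seed mask is empty")
  if (all(field$qa == 0)) {
    warning("orientation field is all zero; no streamlines tracked")
    return(streamline_set())
  }
  grid <- field$grid
  seeds <- with_seed(params$rng_seed, {
    pick <- mask_idx[sample.int(length(mask_idx), params$seed_count,
                                replace = TRUE)]
    ijk <- arrayInd(pick, grid$shape) - 1
    ijk <- ijk + matrix(stats::runif(3 * params$seed_count, -0.5, 0.5),
                        ncol = 3)
    voxel_to_world(grid, ijk)
  })
  res <- cpp_track(as.numeric(field$dir), as.numeric(field$qa), grid$shape,
                   solve(grid$affine), seeds,
                   params$qa_threshold, params$angular_threshold_deg,
                   params$step_mm, params$smoothing, params$max_length_mm)
  tracks <- streamline_set(res$coords, res$npts,
                           data.frame(subdivision = rep(NA_character_,
                                                        length(res$npts)),
                                      subject = subject, side = side))
  lens <- streamline_lengths(tracks)
  keep <- lens >= params$min_length_mm & lens <= params$max_length_mm
  out <- subset_streamlines(tracks, keep)
  if (verbose)
    message(sprintf(
      "tracked %d seeds: %d retained streamlines (mean length %.1f mm)",
      params$seed_count, n_streamlines(out),
      if (n_streamlines(out)) mean(lens[keep]) else NA_real_))
  out
}

#' Filter streamlines by region-of-interest passage and length
#'
#' Retains streamlines that traverse at least one ROI voxel and whose arc
#' length lies in the given window, tagging them with the ROI's division
#' label (seed/ROI combinations select the upper or lower division).
#'
#' @param tracks a [streamline_set()].
#' @param roi_mask 0/1 [label_volume()] (or logical array with a grid
#'   attached via `grid`).
#' @param division subdivision tag to assign to retained streamlines
#'   (e.g. `"ORu"`).
#' @param min_length_mm,max_length_mm length window in mm.
#' @param grid grid of `roi_mask` when given as a bare array.
#' @return the filtered, tagged [streamline_set()].
#' @export
filter_streamlines <- function(tracks, roi_mask, division = NA_character_,
                               min_length_mm = 30, max_length_mm = 300,
                               grid = NULL) {
  stopifnot(inherits(tracks, "streamline_set"))
  if (inherits(roi_mask, "ora_volume")) {
    grid <- roi_mask$grid
    roi <- roi_mask$data
  } else {
    stopifnot(inherits(grid, "volume_grid"))
    roi <- roi_mask
  }
  if (!any(roi > 0)) {
    warning("ROI mask is empty; no streamlines retained")
    return(subset_streamlines(tracks, logical(n_streamlines(tracks))))
  }
  if (!n_streamlines(tracks)) return(tracks)
  vsets <- cpp_streamline_voxels(tracks$coords, tracks$npts, grid$shape,
                                 solve(grid$affine),
                                 min(voxel_sizes(grid)) / 2)
  roi_lin <- which(as.vector(roi) > 0)
  hits <- vapply(vsets, function(v) any(v %in% roi_lin), logical(1))
  lens <- streamline_lengths(tracks)
  keep <- hits & lens >= min_length_mm & lens <= max_length_mm
  out <- subset_streamlines(tracks, keep)
  if (n_streamlines(out)) out$tags$subdivision <- division
  out
}
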