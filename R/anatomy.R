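#' Anterior ridge of Meyer's loop
#'
#' The most anterior point (maximal world Y) of the side's Meyer's-loop
#' portion, defined as everything anterior to the LGN coronal plane. Works
#' on streamline sets (vertex-based) or label/TDI volumes (voxel-center
#' based). Ties resolve to the smallest `|X|` (closest to the midline).
#'
#' @param x a [streamline_set()] or a [label_volume()] / [tdi_volume()].
#' @param side `"left"` or `"right"`.
#' @param lgn_y world Y of the LGN plane delimiting the loop portion; points
#'   at or posterior to this plane are ignored.
#' @return world point (length-3 numeric) of the ridge.
#' @export
anterior_ridge <- function(x, side, lgn_y = -Inf) {
  pts <- if (inherits(x, "streamline_set")) {
    sel <- if (all(is.na(x$tags$side))) rep(TRUE, n_streamlines(x))
           else x$tags$side == side
    if (!any(sel)) stop("no streamlines on the requested side")
    subset_streamlines(x, sel)$coords
  } else {
    idx <- which(region_side_mask(x, side))
    if (!length(idx)) stop("region is empty on the requested side")
    voxel_to_world(x$grid, arrayInd(idx, x$grid$shape) - 1)
  }
  ml <- pts[pts[, 2] > lgn_y, , drop = FALSE]
  if (!nrow(ml))
    stop("no Meyer's-loop portion: nothing anterior to the LGN plane")
  ymax <- max(ml[, 2])
  cand <- ml[ml[, 2] == ymax, , drop = FALSE]
  cand[which.min(abs(cand[, 1])), ]
}

#' Tip-to-ridge distance (dTM)
#'
#' Distance from the anterior tip of the temporal lobe to the anterior ridge
#' of Meyer's loop, measured along the anterior-posterior axis (the surgical
#' "distance from the temporal pole" convention): `Y(tip) - Y(ridge)`.
#' A Euclidean variant is available.
#'
#' @param temporal_tip world point of the anterior temporal tip.
#' @param ridge world point of the anterior ridge (same side).
#' @param euclidean use the full 3-D Euclidean distance instead of the Y
#'   difference.
#' @return distance in mm.
#' @export
measure_dtm <- function(temporal_tip, ridge, euclidean = FALSE) {
  if (euclidean) return(vnorm(as.numeric(temporal_tip) - as.numeric(ridge)))
  unname(temporal_tip[2] - ridge[2])
}

#' LGN-to-ridge distance
#' @param lgn_center world point of the LGN center.
#' @param ridge world point of the anterior ridge.
#' @return Euclidean distance in mm.
#' @export
lgn_to_ridge_distance <- function(lgn_center, ridge) {
  vnorm(as.numeric(lgn_center) - as.numeric(ridge))
}

#' Upper/lower division twist profile
#'
#' For each coronal slab of width `slice_step_mm` spanning the joint
#' anterior-posterior extent of the two divisions, computes the centroid X
#' of the upper (ORu) and lower (ORl) division and emits the signed
#' medial-to-lateral difference (positive = ORu lateral to ORl, medial being
#' toward the X midline), counting the sign changes over slabs containing
#' both divisions. The divisions twisting around each other show exactly one
#' sign change.
#'
#' @param x a [streamline_set()] with `subdivision` tags, or a
#'   [label_volume()].
#' @param side `"left"` or `"right"`.
#' @param slice_step_mm coronal slab width in mm.
#' @param tol_mm centroid-difference noise floor: slabs with
#'   `|diff| <= tol_mm` count as zero when tallying sign changes.
#' @return list with `profile` (data frame: `y_mm`, `x_ORu`, `x_ORl`,
#'   `diff_lateral`) and `sign_changes` (integer).
#' @export
twist_profile <- function(x, side, slice_step_mm = 3, tol_mm = 1) {
  lat <- if (side == "left") -1 else 1
  if (inherits(x, "streamline_set")) {
    sel_side <- if (all(is.na(x$tags$side))) rep(TRUE, n_streamlines(x))
                else x$tags$side == side
    pts_of <- function(div) {
      sel <- sel_side & x$tags$subdivision == div
      if (!any(sel)) stop("division ", div, " absent on the ", side, " side")
      subset_streamlines(x, sel)$coords
    }
    pu <- pts_of("ORu")
    pl <- pts_of("ORl")
  } else {
    lg <- atlas_legend()
    vox_of <- function(code) {
      idx <- which(as.vector(x$data) == code)
      if (!length(idx)) stop("division label ", code, " absent")
      voxel_to_world(x$grid, arrayInd(idx, x$grid$shape) - 1)
    }
    pu <- vox_of(lg[paste0(side, "_ORu")])
    pl <- vox_of(lg[paste0(side, "_ORl")])
  }
  yr <- range(c(pu[, 2], pl[, 2]))
  edges <- seq(yr[1], yr[2] + slice_step_mm, by = slice_step_mm)
  rows <- list()
  for (b in seq_len(length(edges) - 1)) {
    iu <- pu[, 2] >= edges[b] & pu[, 2] < edges[b + 1]
    il <- pl[, 2] >= edges[b] & pl[, 2] < edges[b + 1]
    if (!any(iu) || !any(il)) next
    xu <- mean(pu[iu, 1])
    xl <- mean(pl[il, 1])
    rows[[length(rows) + 1]] <- data.frame(
      y_mm = (edges[b] + edges[b + 1]) / 2,
      x_ORu = xu, x_ORl = xl,
      diff_lateral = lat * (xu - xl)) # positive = ORu lateral to ORl
  }
  if (!length(rows)) stop("no slab contains both divisions")
  profile <- do.call(rbind, rows)
  list(profile = profile,
       sign_changes = count_sign_changes(profile$diff_lateral, tol_mm))
}

#' Geometry report for one side
#'
#' Bundles the anatomical measurements: anterior ridge, dTM, LGN-to-ridge
#' distance, and the twist profile.
#'
#' @param tracks_or_region a [streamline_set()] or [label_volume()].
#' @param side `"left"` or `"right"`.
#' @param lgn_center,temporal_tip landmark world points for the side.
#' @param slice_step_mm slab width for the twist profile.
#' @return a `geometry_report` list.
#' @export
geometry_report <- function(tracks_or_region, side, lgn_center, temporal_tip,
                            slice_step_mm = 3) {
  ridge <- anterior_ridge(tracks_or_region, side, lgn_y = lgn_center[2])
  tw <- twist_profile(tracks_or_region, side, slice_step_mm)
  structure(list(
    side = side,
    anterior_ridge = ridge,
    dtm_mm = measure_dtm(temporal_tip, ridge),
    lgn_to_ridge_mm = lgn_to_ridge_distance(lgn_center, ridge),
    twist = tw), class = "geometry_report")
}

#' @export
print.geometry_report <- function(x, ...) {
  cat(sprintf("<geometry_report> %s side\n", x$side))
  cat(sprintf("  anterior ridge: (%.1f, %.1f, %.1f) mm\n",
              x$anterior_ridge[1], x$anterior_ridge[2], x$anterior_ridge[3]))
  cat(sprintf("  dTM %.2f mm, LGN-to-ridge %.2f mm, twist sign changes: %d\n",
              x$dtm_mm, x$lgn_to_ridge_mm, x$twist$sign_changes))
  invisible(x)
}
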