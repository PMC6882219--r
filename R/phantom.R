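#' Phantom specification for the synthetic optic-radiation bundle
#'
#' Defines the generative geometry of a synthetic Meyer's-loop bundle: a
#' curving, fanning bundle that leaves an "LGN" point through a short stub
#' (the optic-tract analogue), turns sharply onto the loop, sweeps anteriorly
#' around a "temporal horn" up to a prescribed anterior ridge, and then runs
#' posteriorly to two cortical target zones (upper division ORu to a
#' cuneus-like target, lower division ORl to a lingual-like target) with a
#' twisting arrangement between the divisions.
#'
#' The anterior reach is parameterized through `dtm_mm`, the distance from
#' the anterior temporal-lobe tip to the anterior ridge of the loop, so that
#' `loop_apex_y = temporal_tip_y - dtm_mm` per side; this is the quantity the
#' recovery experiments measure back.
#'
#' @param grid a [volume_grid()] covering the phantom.
#' @param lgn_center named list (`left`, `right`) of world LGN points in mm.
#' @param temporal_tip named list of anterior temporal-tip landmarks.
#' @param dtm_mm named numeric (`left`, `right`): true tip-to-ridge distance
#'   per side in mm (anterior-posterior axis).
#' @param fan_half_angle fanning half-angle at the origin, degrees in (0, 90).
#' @param sharp_angle turn between the inflow stub and the initial loop
#'   direction, degrees.
#' @param twist_gain lateral crossover magnitude (mm) of the upper vs lower
#'   division along Y; 0 disables the twist.
#' @param n_streamlines streamlines per division (per side).
#' @param jitter_sd per-point Gaussian positional noise, mm.
#' @param rng_seed integer seed making the bundle reproducible.
#' @return an object of class `phantom_spec`.
#' @export
phantom_spec <- function(grid = default_phantom_grid(),
                         lgn_center = list(left = c(-22, -28, 2),
                                           right = c(22, -28, 2)),
                         temporal_tip = list(left = c(-34, 25, -12),
                                             right = c(34, 25, -12)),
                         dtm_mm = c(left = 23.1, right = 26.41),
                         fan_half_angle = 12,
                         sharp_angle = 80,
                         twist_gain = 1.5,
                         n_streamlines = 400,
                         jitter_sd = 0.15,
                         rng_seed = 42L) {
  stopifnot(inherits(grid, "volume_grid"))
  stopifnot(fan_half_angle > 0, fan_half_angle < 90)
  stopifnot(n_streamlines >= 1, jitter_sd >= 0, twist_gain >= 0)
  spec <- structure(list(grid = grid, lgn_center = lgn_center,
                         temporal_tip = temporal_tip,
                         dtm_mm = dtm_mm,
                         fan_half_angle = fan_half_angle,
                         sharp_angle = sharp_angle, twist_gain = twist_gain,
                         n_streamlines = n_streamlines, jitter_sd = jitter_sd,
                         rng_seed = as.integer(rng_seed)),
                    class = "phantom_spec")
  for (side in c("left", "right")) {
    apex_y <- loop_apex_y(spec, side)
    if (!(apex_y > lgn_center[[side]][2]))
      stop("degenerate geometry on the ", side,
           " side: loop apex must lie anterior to the LGN (apex Y = ",
           signif(apex_y, 4), ", LGN Y = ", lgn_center[[side]][2], ")")
    if (!(apex_y < temporal_tip[[side]][2]))
      stop("degenerate geometry on the ", side,
           " side: loop apex must lie posterior to the temporal tip")
  }
  spec
}

#' World Y of the intended anterior ridge for one side
#' @param spec a [phantom_spec()].
#' @param side `"left"` or `"right"`.
#' @return numeric scalar, world mm.
#' @export
loop_apex_y <- function(spec, side = c("left", "right")) {
  side <- match.arg(side)
  unname(spec$temporal_tip[[side]][2] - spec$dtm_mm[[side]])
}

#' @export
print.phantom_spec <- function(x, ...) {
  cat("<phantom_spec>\n")
  cat(sprintf("  dTM: left %.2f mm, right %.2f mm (apex Y %.2f / %.2f)\n",
              x$dtm_mm[["left"]], x$dtm_mm[["right"]],
              loop_apex_y(x, "left"), loop_apex_y(x, "right")))
  cat(sprintf("  fan %.1f deg, sharp angle %.1f deg, twist gain %.1f mm\n",
              x$fan_half_angle, x$sharp_angle, x$twist_gain))
  cat(sprintf("  %d streamlines/division, jitter %.2f mm, seed %d\n",
              x$n_streamlines, x$jitter_sd, x$rng_seed))
  invisible(x)
}

# deterministic geometric scaffolding of one side: control anchors per
# division plus landmark points. lat = outward unit sign on X.
phantom_geometry <- function(spec, side) {
  lat <- if (side == "left") -1 else 1
  lgn <- as.numeric(spec$lgn_center[[side]])
  tip <- as.numeric(spec$temporal_tip[[side]])
  apex_y <- loop_apex_y(spec, side)
  # the loop wraps vertically around the temporal-horn analogue: the
  # ascending limb runs anteriorly over the horn roof, the crest dives at
  # apex_y, and the return limb passes below the horn before sweeping
  # posteriorly; the limbs are separated in Z so the hairpin stays resolvable
  list(
    side = side, lat = lat, lgn = lgn, tip = tip, apex_y = apex_y,
    pre_apex = list(ORu = c(lat * 33, apex_y - 12, 17),
                    ORl = c(lat * 33, apex_y - 12, 9)),
    apex = list(ORu = c(lat * 34, apex_y, 0),
                ORl = c(lat * 34, apex_y, -8)),
    post_apex = list(ORu = c(lat * 35, apex_y - 12, -17),
                     ORl = c(lat * 35, apex_y - 12, -25)),
    mid = list(ORu = c(lat * 37, -36, -8), ORl = c(lat * 37, -36, -18)),
    target = list(ORu = c(lat * 12, -72, 4), ORl = c(lat * 12, -72, -18)),
    twist_center_y = -30, twist_length_y = 12,
    stub_mm = 3, takeoff_mm = 4, crest_depth = 10, apex_overshoot = 4
  )
}

# reference anterior-ridge point of the noise-free template (per side):
# the crest point of the zero-offset realized fiber (averaged over divisions)
phantom_apex_point <- function(spec, side) {
  pts <- lapply(c("ORu", "ORl"), function(dv) {
    p <- phantom_reference_fiber(spec, side, dv)
    p[which.max(p[, 2]), ]
  })
  (pts[[1]] + pts[[2]]) / 2
}

# streamlines per division; a helper for tests and sizing
phantom_division_count <- function(spec) spec$n_streamlines

# signed lateral X-offset implementing the ORu/ORl twist along Y
twist_offset <- function(y, division, geom, twist_gain) {
  s_div <- if (division == "ORu") 1 else -1
  s_div * geom$lat * twist_gain *
    tanh((y - geom$twist_center_y) / geom$twist_length_y)
}

# sample one centerline through the control knots; returns n x 3 matrix
phantom_centerline <- function(geom, division, apex_off, target_off,
                               twist_gain, apex_drop = 0, spacing_mm = 0.5) {
  u0 <- unitv(geom$pre_apex[[division]] - geom$lgn)
  # stub chosen so that turning onto the loop take-off spans the sharp angle
  rot <- rot_axis(3, -geom$lat * geom$sharp_angle_deg)
  u_stub <- as.numeric(rot %*% u0)
  p0 <- geom$lgn
  p1 <- p0 + geom$stub_mm * u_stub
  p2 <- p1 + geom$takeoff_mm * u0
  # the apex knot is overshot anteriorly so the momentum-realized path,
  # which lags the centerline, still reaches its clamp level exactly
  off_a <- c(apex_off[1], -apex_drop, apex_off[2])
  off_t <- c(target_off[1], 0, target_off[2])
  p3 <- geom$pre_apex[[division]] + off_a
  p4 <- geom$apex[[division]] + off_a + c(0, geom$apex_overshoot, 0)
  p5 <- geom$post_apex[[division]] + off_a
  p6 <- geom$mid[[division]] + (off_a + off_t) / 2
  p7 <- geom$target[[division]] + off_t
  knots <- rbind(p0, p1, p2, p3, p4, p5, p6, p7)
  tk <- c(0, cumsum(sqrt(rowSums(diff(knots)^2))))
  ts <- seq(0, tk[length(tk)], by = spacing_mm)
  x <- stats::spline(tk, knots[, 1], xout = ts, method = "natural")$y
  y <- stats::spline(tk, knots[, 2], xout = ts, method = "natural")$y
  z <- stats::spline(tk, knots[, 3], xout = ts, method = "natural")$y
  x <- x + twist_offset(y, division, geom, twist_gain)
  cbind(x, y, z)
}

# realize one fiber: momentum flow along the centerline tangents (the same
# direction-update rule a deterministic tracker applies), then clamp the
# anterior crest at this fiber's own ridge level
phantom_fiber <- function(geom, division, apex_off, target_off, twist_gain,
                          apex_drop = 0, step_mm = 0.5, smoothing = 0.8) {
  cl <- phantom_centerline(geom, division, apex_off, target_off, twist_gain,
                           apex_drop, spacing_mm = step_mm)
  pts <- cpp_momentum_realize(cl, step_mm, smoothing)
  pts[, 2] <- pmin(pts[, 2], geom$apex_y - apex_drop)
  pts
}

# noise-free reference fiber of a division (zero fan offsets, zero drop);
# anchors the realized target zones and the anterior-ridge reference point
phantom_reference_fiber <- function(spec, side, division) {
  geom <- phantom_geometry(spec, side)
  geom$sharp_angle_deg <- spec$sharp_angle
  phantom_fiber(geom, division, c(0, 0), c(0, 0), spec$twist_gain)
}

#' Generate the phantom bundle for one side
#'
#' Produces `2 * n_streamlines` polylines (upper and lower division), each
#' starting at the LGN, turning by the sharp angle onto the loop, cresting
#' exactly at the side's anterior ridge (up to jitter), and descending to the
#' division's cortical target. Fanning is realized by perturbing the apex and
#' target control points inside a disc whose angular size at the origin is
#' the fan half-angle; the ORu/ORl twist by an X-offset that changes sign at
#' a fixed Y level.
#'
#' @param spec a [phantom_spec()].
#' @param side `"left"` or `"right"`.
#' @return a [streamline_set()] tagged with `subdivision` (`ORu`/`ORl`) and
#'   `side`.
#' @export
make_phantom_bundle <- function(spec, side = c("left", "right")) {
  side <- match.arg(side)
  geom <- phantom_geometry(spec, side)
  geom$sharp_angle_deg <- spec$sharp_angle
  n <- spec$n_streamlines
  seed <- spec$rng_seed + if (side == "left") 0L else 1L
  with_seed(seed, {
    pieces <- list()
    for (division in c("ORu", "ORl")) {
      r_apex <- tan(spec$fan_half_angle * pi / 180) *
        vnorm(geom$apex[[division]] - geom$lgn)
      r_targ <- tan(spec$fan_half_angle * pi / 180) *
        vnorm(geom$target[[division]] - geom$lgn)
      for (i in seq_len(n)) {
        # uniform offsets in a disc of the fan radius (X-Z plane); crest
        # depths are spread deterministically so the bundle envelope reaches
        # the ridge exactly while the anterior extension thins out
        th <- stats::runif(2, 0, 2 * pi)
        rr <- sqrt(stats::runif(2)) * c(r_apex, r_targ)
        apex_off <- rr[1] * c(cos(th[1]), sin(th[1]))
        targ_off <- rr[2] * c(cos(th[2]), sin(th[2]))
        drop_i <- geom$crest_depth * (i - 1) / max(1, n - 1)
        pts <- phantom_fiber(geom, division, apex_off, targ_off,
                             spec$twist_gain, apex_drop = drop_i)
        if (spec$jitter_sd > 0)
          pts <- pts + matrix(stats::rnorm(length(pts), 0, spec$jitter_sd),
                              ncol = 3)
        pieces[[length(pieces) + 1L]] <-
          list(pts = pts, division = division)
      }
    }
    coords <- do.call(rbind, lapply(pieces, `[[`, "pts"))
    streamline_set(coords,
                   vapply(pieces, function(p) nrow(p$pts), integer(1)),
                   data.frame(subdivision = vapply(pieces, `[[`, "",
                                                   "division"),
                              subject = NA_character_,
                              side = side))
  })
}

#' Tracking region masks and landmarks for one phantom side
#'
#' Builds the seed sphere at the LGN and the two division target boxes
#' (upper/lower region of interest), mirroring the seed/ROI logic used for
#' optic-radiation tracking, plus the temporal-tip landmark.
#'
#' @param spec a [phantom_spec()].
#' @param side `"left"` or `"right"`.
#' @param seed_radius_mm radius of the LGN seed sphere.
#' @param roi_half_mm length-3 half-extent of each target box (X, Y, Z mm).
#' @param centers optional list overriding the geometric centers, with
#'   elements `lgn`, `ORu`, `ORl`, `tip` (used when landmarks have been
#'   mapped into an individual space).
#' @return list with `seed_mask`, `roi_upper_mask`, `roi_lower_mask`
#'   (0/1 [label_volume()]s on the spec grid) and `temporal_tip_landmark`.
#' @export
make_region_masks <- function(spec, side = c("left", "right"),
                              seed_radius_mm = 5,
                              roi_half_mm = c(8, 5, 7),
                              centers = NULL) {
  side <- match.arg(side)
  geom <- phantom_geometry(spec, side)
  if (is.null(centers)) {
    # target zones anchored at the realized reference-fiber endpoints
    ends <- lapply(c("ORu", "ORl"), function(dv) {
      p <- phantom_reference_fiber(spec, side, dv)
      p[nrow(p), ]
    })
    centers <- list(lgn = geom$lgn, ORu = ends[[1]], ORl = ends[[2]],
                    tip = geom$tip)
  }
  grid <- spec$grid
  ctr <- grid_voxel_centers(grid)
  seed <- sqrt(rowSums(sweep(ctr, 2, centers$lgn)^2)) <= seed_radius_mm
  in_box <- function(center) {
    abs(ctr[, 1] - center[1]) <= roi_half_mm[1] &
      abs(ctr[, 2] - center[2]) <= roi_half_mm[2] &
      abs(ctr[, 3] - center[3]) <= roi_half_mm[3]
  }
  upper <- in_box(centers$ORu)
  lower <- in_box(centers$ORl)
  if (any(seed & upper) || any(seed & lower) || any(upper & lower))
    stop("seed and ROI masks must be pairwise disjoint; ",
         "reduce seed_radius_mm or roi_half_mm")
  mk <- function(v) label_volume(array(as.integer(v), grid$shape), grid)
  list(seed_mask = mk(seed), roi_upper_mask = mk(upper),
       roi_lower_mask = mk(lower),
       temporal_tip_landmark = centers$tip)
}

#' Rasterize a bundle into an orientation/QA field
#'
#' Every voxel traversed by at least one streamline segment receives the
#' normalized mean of the sign-aligned segment directions and a QA value
#' equal to its distinct-streamline traversal count scaled so the maximum is
#' 1; untraversed voxels keep QA 0 and a zero direction.
#'
#' @param bundle a non-empty [streamline_set()].
#' @param grid a [volume_grid()] covering the bundle's bounding box.
#' @return an `orientation_field` object (list with `grid`, a
#'   `c(shape, 3)` direction array `dir`, and a QA array `qa`).
#' @export
rasterize_orientation_field <- function(bundle, grid) {
  stopifnot(inherits(bundle, "streamline_set"), n_streamlines(bundle) > 0)
  vox <- world_to_voxel(grid, bundle$coords)
  lo <- floor(apply(vox, 2, min) + 0.5)
  hi <- floor(apply(vox, 2, max) + 0.5)
  if (any(lo < 0) || any(hi > grid$shape - 1))
    stop(sprintf(
      "bundle extends outside the grid: voxel extent [%s] to [%s] vs shape [%s]",
      paste(lo, collapse = ", "), paste(hi, collapse = ", "),
      paste(grid$shape, collapse = ", ")))
  res <- cpp_rasterize_field(bundle$coords, bundle$npts, grid$shape,
                             solve(grid$affine), min(voxel_sizes(grid)) / 2)
  qa <- as.numeric(res$count)
  if (max(qa) > 0) qa <- qa / max(qa)
  orientation_field(array(res$dirs, c(grid$shape, 3L)),
                    array(qa, grid$shape), grid)
}

#' Orientation field container
#' @param dir `c(shape, 3)` array of per-voxel unit directions (zero where
#'   unset).
#' @param qa non-negative scalar array on the grid.
#' @param grid a [volume_grid()].
#' @return an `orientation_field` object.
#' @export
orientation_field <- function(dir, qa, grid) {
  stopifnot(inherits(grid, "volume_grid"))
  dir <- array(as.numeric(dir), c(grid$shape, 3L))
  qa <- array(as.numeric(qa), grid$shape)
  if (any(qa < 0)) stop("QA must be non-negative everywhere")
  n2 <- sqrt(matrix(dir, ncol = 3)[, 1]^2 + matrix(dir, ncol = 3)[, 2]^2 +
               matrix(dir, ncol = 3)[, 3]^2)
  set <- qa > 0
  if (any(set) && any(abs(n2[as.vector(set)] - 1) > 1e-6))
    stop("directions must have unit norm wherever QA > 0")
  structure(list(grid = grid, dir = dir, qa = qa),
            class = "orientation_field")
}

#' @export
print.orientation_field <- function(x, ...) {
  cat(sprintf("<orientation_field> %s voxels, %d with QA > 0\n",
              paste(x$grid$shape, collapse = " x "), sum(x$qa > 0)))
  invisible(x)
}
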