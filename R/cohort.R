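#' Random subject transform (affine + smooth displacement field)
#'
#' Draws the ground-truth spatial transform that turns the template bundle
#' into one synthetic subject: a rotation (about the grid center), an
#' anisotropic scale, and a translation, followed by a smooth band-limited
#' displacement field (Gaussian-smoothed white noise with the requested
#' correlation length, rescaled to the requested peak amplitude). The
#' generated warp is checked to be diffeomorphic: the Jacobian determinant of
#' `w -> w + D(w)` must be positive at every voxel.
#'
#' @param rng_seed integer seed.
#' @param max_rot_deg per-axis rotation bound, degrees.
#' @param max_scale_dev per-axis scale bound (scales drawn in `1 +/- dev`).
#' @param max_shift_mm per-axis translation bound, mm.
#' @param warp_amp_mm peak displacement magnitude of the dense field, mm
#'   (0 disables the field).
#' @param warp_scale_mm correlation length of the field, mm.
#' @param grid [volume_grid()] carrying the displacement field.
#' @return a [spatial_transform()].
#' @export
make_subject_transform <- function(rng_seed, max_rot_deg = 5,
                                   max_scale_dev = 0.05, max_shift_mm = 3,
                                   warp_amp_mm = 2.5, warp_scale_mm = 20,
                                   grid = default_phantom_grid()) {
  stopifnot(max_rot_deg >= 0, max_scale_dev >= 0, max_shift_mm >= 0,
            warp_amp_mm >= 0, warp_scale_mm > 0)
  with_seed(rng_seed, {
    rot_deg <- stats::runif(3, -max_rot_deg, max_rot_deg)
    scales <- stats::runif(3, 1 - max_scale_dev, 1 + max_scale_dev)
    shift <- stats::runif(3, -max_shift_mm, max_shift_mm)
    center <- voxel_to_world(grid, (grid$shape - 1) / 2)[1, ]
    r <- rot_axis(1, rot_deg[1]) %*% rot_axis(2, rot_deg[2]) %*%
      rot_axis(3, rot_deg[3])
    lin <- r %*% diag(scales)
    aff <- diag(4)
    aff[1:3, 1:3] <- lin
    # rotation/scale about the grid center, then translate
    aff[1:3, 4] <- center - lin %*% center + shift
    disp <- NULL
    if (warp_amp_mm > 0) {
      sigma_vox <- warp_scale_mm / voxel_sizes(grid)
      disp <- array(0, c(grid$shape, 3L))
      for (c in 1:3) {
        noise <- array(stats::rnorm(prod(grid$shape)), grid$shape)
        disp[, , , c] <- gauss_smooth3d(noise, sigma_vox)
      }
      # taper the field to zero at the grid boundary so the warp (and its
      # fixed-point inverse) is well defined on the whole grid
      disp <- disp * edge_taper(grid$shape, width = 5)
      mag <- sqrt(rowSums(matrix(disp, ncol = 3)^2))
      peak <- max(mag)
      if (peak > 0) disp <- disp * (warp_amp_mm / peak)
    }
    t <- spatial_transform(aff, disp, if (is.null(disp)) NULL else grid,
                           provenance = sprintf("subject transform seed %d",
                                                rng_seed))
    if (!is.null(disp)) {
      jmin <- min_jacobian_det(disp, grid)
      if (jmin <= 0)
        stop(sprintf(
          "generated warp is not diffeomorphic (min Jacobian det %.3f); use a smaller warp_amp_mm",
          jmin))
    }
    t
  })
}

# smooth [0,1] window that falls to zero at the faces of the grid
edge_taper <- function(shape, width = 5) {
  ramp <- function(n) {
    d <- pmin(seq_len(n) - 1, n - seq_len(n))
    pmin(1, d / width)
  }
  w <- outer(outer(ramp(shape[1]), ramp(shape[2]), pmin),
             array(ramp(shape[3]), shape[3]), pmin)
  array(w, c(shape, 1))[, , , c(1, 1, 1)]
}

# minimum Jacobian determinant of w -> w + D(w) over the grid interior,
# via central differences in world coordinates
min_jacobian_det <- function(disp, grid) {
  sh <- grid$shape
  ainv_lin <- solve(grid$affine)[1:3, 1:3]
  # voxel-space gradients of each displacement component
  grad <- array(0, c(sh, 3, 3)) # [..., component, voxel axis]
  for (c in 1:3) {
    d <- disp[, , , c]
    grad[2:(sh[1] - 1), , , c, 1] <-
      (d[3:sh[1], , ] - d[1:(sh[1] - 2), , ]) / 2
    grad[, 2:(sh[2] - 1), , c, 2] <-
      (d[, 3:sh[2], ] - d[, 1:(sh[2] - 2), ]) / 2
    grad[, , 2:(sh[3] - 1), c, 3] <-
      (d[, , 3:sh[3]] - d[, , 1:(sh[3] - 2)]) / 2
  }
  n <- prod(sh)
  g <- matrix(grad, n, 9) # columns: (c, axis) pairs in array order
  # world-space gradient: dD_c/dw = dD_c/dv %*% ainv_lin
  j <- matrix(0, n, 9)
  for (c in 1:3) {
    gv <- g[, c + 3 * (0:2)] # dD_c/dv over the three voxel axes
    j[, c + 3 * (0:2)] <- gv %*% ainv_lin
  }
  # det(I + J) per voxel, J[c, d] = j[, c + 3*(d-1)]
  a11 <- 1 + j[, 1]; a12 <- j[, 4]; a13 <- j[, 7]
  a21 <- j[, 2]; a22 <- 1 + j[, 5]; a23 <- j[, 8]
  a31 <- j[, 3]; a32 <- j[, 6]; a33 <- 1 + j[, 9]
  det <- a11 * (a22 * a33 - a23 * a32) - a12 * (a21 * a33 - a23 * a31) +
    a13 * (a21 * a32 - a22 * a31)
  min(det)
}

#' Generate a phantom cohort with known ground truth
#'
#' Each subject is a smoothly deformed copy of the template bundle: the
#' template streamlines, landmarks and region centers are mapped through a
#' per-subject ground-truth transform, and the deformed bundle is rasterized
#' into the subject's orientation/QA field. The returned truth record holds
#' the template bundle, all transforms, per-subject landmarks, and the true
#' per-side/per-subject anterior-ridge geometry used by the recovery tests.
#'
#' @param n_subjects cohort size (the default emulates a 30-participant
#'   group study).
#' @param spec a [phantom_spec()].
#' @param rng_seed integer seed for the per-subject transforms.
#' @param deform named list of amplitude arguments passed to
#'   [make_subject_transform()] (set all to 0 for identity transforms).
#' @param rasterize logical: attach each subject's orientation field
#'   (disable to save time when only geometry is needed).
#' @return list with elements `truth` (class `cohort_truth`) and `subjects`
#'   (per-subject list: `bundle`, `field`, `masks` per side, `landmarks`,
#'   `transform`).
#' @export
make_cohort <- function(n_subjects = 30, spec = phantom_spec(),
                        rng_seed = spec$rng_seed,
                        deform = list(), rasterize = TRUE) {
  stopifnot(n_subjects >= 1)
  template <- concat_streamlines(list(make_phantom_bundle(spec, "left"),
                                      make_phantom_bundle(spec, "right")))
  def_args <- utils::modifyList(
    list(max_rot_deg = 5, max_scale_dev = 0.05, max_shift_mm = 3,
         warp_amp_mm = 2.5, warp_scale_mm = 20),
    deform)
  apex_pts <- list(left = phantom_apex_point(spec, "left"),
                   right = phantom_apex_point(spec, "right"))
  transforms <- vector("list", n_subjects)
  subjects <- vector("list", n_subjects)
  for (i in seq_len(n_subjects)) {
    t_i <- do.call(make_subject_transform,
                   c(list(rng_seed = rng_seed + i, grid = spec$grid),
                     def_args))
    transforms[[i]] <- t_i
    bundle <- map_streamline_points(template, function(p)
      apply_to_points(t_i, p, warn_outside = FALSE))
    bundle$tags$subject <- sprintf("sub-%02d", i)
    landmarks <- list()
    masks <- list()
    for (side in c("left", "right")) {
      geom <- phantom_geometry(spec, side)
      mapped <- apply_to_points(
        t_i, rbind(geom$lgn, geom$tip, geom$target$ORu, geom$target$ORl,
                   apex_pts[[side]]),
        warn_outside = FALSE)
      landmarks[[side]] <- list(lgn_center = mapped[1, ],
                                temporal_tip = mapped[2, ],
                                apex = mapped[5, ])
      masks[[side]] <- make_region_masks(
        spec, side,
        centers = list(lgn = mapped[1, ], tip = mapped[2, ],
                       ORu = mapped[3, ], ORl = mapped[4, ]))
    }
    subjects[[i]] <- list(
      bundle = bundle,
      field = if (rasterize) rasterize_orientation_field(bundle, spec$grid),
      masks = masks,
      landmarks = landmarks,
      transform = t_i)
  }
  truth <- structure(list(
    spec = spec,
    template_bundle = template,
    transforms = transforms,
    landmarks = lapply(subjects, `[[`, "landmarks"),
    true_dtm = spec$dtm_mm,
    template_apex = apex_pts,
    subject_dtm = vapply(subjects, function(s)
      c(left = s$landmarks$left$temporal_tip[2] - s$landmarks$left$apex[2],
        right = s$landmarks$right$temporal_tip[2] - s$landmarks$right$apex[2]),
      numeric(2))),
    class = "cohort_truth")
  list(truth = truth, subjects = subjects)
}

#' @export
print.cohort_truth <- function(x, ...) {
  cat(sprintf("<cohort_truth> %d subjects; template dTM left %.2f / right %.2f mm\n",
              length(x$transforms), x$true_dtm[["left"]],
              x$true_dtm[["right"]]))
  invisible(x)
}

#' Write a cohort-truth sidecar as JSON
#'
#' Records the generative parameters and ground-truth geometry (transform
#' provenance, per-subject landmarks and true dTM values) in a plain-text
#' sidecar next to the generated volumes.
#'
#' @param truth a `cohort_truth` from [make_cohort()].
#' @param path output JSON path.
#' @return the path, invisibly.
#' @export
write_cohort_truth <- function(truth, path) {
  payload <- list(
    n_subjects = length(truth$transforms),
    true_dtm = as.list(truth$true_dtm),
    template_apex = truth$template_apex,
    subject_dtm = t(truth$subject_dtm),
    landmarks = truth$landmarks,
    spec = truth$spec[setdiff(names(truth$spec), "grid")])
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
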