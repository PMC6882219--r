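#' Split a tagged streamline set into atlas divisions
#'
#' Uses the `side` and `subdivision` tags to produce the four atlas groups
#' (`left_ORu`, `right_ORu`, `left_ORl`, `right_ORl`), dropping untagged
#' streamlines.
#'
#' @param tracks a [streamline_set()] with `side` and `subdivision` tags.
#' @return named list of [streamline_set()]s (possibly empty divisions are
#'   omitted).
#' @export
split_divisions <- function(tracks) {
  out <- list()
  for (side in c("left", "right"))
    for (div in c("ORu", "ORl")) {
      sel <- !is.na(tracks$tags$side) & tracks$tags$side == side &
        !is.na(tracks$tags$subdivision) & tracks$tags$subdivision == div
      if (any(sel))
        out[[paste0(side, "_", div)]] <- subset_streamlines(tracks, sel)
    }
  out
}

#' Track one subject's optic radiations
#'
#' Runs the deterministic tracker from the subject's LGN seed mask for each
#' side and splits the result into upper/lower divisions with the ROI
#' filter.
#'
#' @param field the subject's `orientation_field`.
#' @param masks per-side mask lists as produced by [make_region_masks()]
#'   (named `left`, `right`).
#' @param params a [tracking_params()].
#' @param subject subject tag for the output.
#' @return a tagged [streamline_set()] with both sides and divisions.
#' @export
track_subject <- function(field, masks, params, subject = NA_character_) {
  pieces <- list()
  for (side in names(masks)) {
    raw <- track_streamlines(field, params, masks[[side]]$seed_mask,
                             side = side, subject = subject)
    up <- filter_streamlines(raw, masks[[side]]$roi_upper_mask, "ORu",
                             params$min_length_mm, params$max_length_mm)
    lo <- filter_streamlines(raw, masks[[side]]$roi_lower_mask, "ORl",
                             params$min_length_mm, params$max_length_mm)
    pieces <- c(pieces, list(up, lo))
  }
  concat_streamlines(pieces)
}

#' Build the atlas volumes from merged groups
#'
#' Merges the per-subject groups of fibers, assigns the four-region label
#' volume and computes the merged tract density image.
#'
#' @param groups list of tagged [streamline_set()]s (one per subject, or
#'   already-merged pieces).
#' @param grid atlas [volume_grid()].
#' @param min_subject_support passed to [build_label_volume()].
#' @return list with `labels` ([label_volume()]), `tdi` ([tdi_volume()]) and
#'   `merged` (the merged [streamline_set()]).
#' @export
atlas_from_groups <- function(groups, grid, min_subject_support = 1L) {
  merged <- merge_groups(groups)
  divisions <- split_divisions(merged)
  labels <- build_label_volume(divisions, grid, min_subject_support)
  tdi <- compute_tdi(merged, grid)
  list(labels = labels, tdi = tdi, merged = merged)
}

#' Correspondence-rate report for one labeled subject side
#'
#' The complete per-side accuracy readout: middle-third slab, maximal
#' tract-density voxels, correspondence rate, shift-tolerance profile and
#' safety-zone check.
#'
#' @param tdi the subject's [tdi_volume()] (individual-space tracking
#'   result).
#' @param labels the warped atlas [label_volume()] in the same space.
#' @param side `"left"` or `"right"`.
#' @param max_offset_mm,step_mm shift-profile parameters (see
#'   [shifted_cr_profile()]); `shift = FALSE` skips the profile.
#' @param margin_mm safety-zone margin.
#' @param shift compute the shift profile.
#' @param per_slice passed to [max_density_voxels()].
#' @return list with `cr`, `max_voxels`, `safety_pass`, and (optionally)
#'   `profile` and `tolerable_cr`.
#' @export
evaluate_subject_side <- function(tdi, labels, side, max_offset_mm = 10,
                                  step_mm = NULL, margin_mm = 5,
                                  shift = TRUE, per_slice = TRUE) {
  slab <- middle_third_slab(tdi, side)
  mv <- max_density_voxels(tdi, slab, per_slice)
  cr <- correspondence_rate(mv, labels, side)
  safety <- safety_zone_check(labels, side, mv, margin_mm)
  out <- list(side = side, cr = cr, max_voxels = mv,
              safety_pass = safety$pass)
  if (shift) {
    prof <- shifted_cr_profile(tdi, labels, side, max_offset_mm, step_mm,
                               per_slice)
    out$profile <- prof$profile
    out$tolerable_cr <- prof$tolerable_cr
  }
  out
}

#' Cohort correspondence-rate summary
#'
#' Pools per-side CR values, reports mean and standard deviation and the
#' bootstrap representativeness check.
#'
#' @param cr_values numeric vector of per-side CR values in `[0, 1]`.
#' @param n_boot,confidence,rng_seed bootstrap settings (see
#'   [bootstrap_mean_ci()]).
#' @return a `cr_report` list: `cr_values`, `mean`, `sd`, `ci_low`,
#'   `ci_high`, `mean_inside`.
#' @export
cr_report <- function(cr_values, n_boot = 10000L, confidence = 0.95,
                      rng_seed = 1L) {
  stopifnot(all(cr_values >= 0), all(cr_values <= 1))
  bs <- bootstrap_mean_ci(cr_values, n_boot, confidence, rng_seed)
  structure(list(cr_values = cr_values, mean = mean(cr_values),
                 sd = stats::sd(cr_values), ci_low = bs$ci_low,
                 ci_high = bs$ci_high, mean_inside = bs$mean_inside),
            class = "cr_report")
}

#' @export
print.cr_report <- function(x, ...) {
  cat(sprintf(
    "<cr_report> %d sides: CR %.2f%% +/- %.2f%%, bootstrap CI [%.2f%%, %.2f%%], mean inside: %s\n",
    length(x$cr_values), 100 * x$mean, 100 * x$sd, 100 * x$ci_low,
    100 * x$ci_high, x$mean_inside))
  invisible(x)
}
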