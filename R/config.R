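#' Read a phantom specification from a YAML config file
#'
#' The config is a flat key-value document mirroring the [phantom_spec()]
#' arguments. Recognized keys (all optional; missing keys keep the package
#' defaults):
#'
#' ```yaml
#' voxel_mm: 1.5            # isotropic grid resolution
#' dtm_left: 23.1           # true tip-to-ridge distance, left (mm)
#' dtm_right: 26.41
#' fan_half_angle: 8        # degrees
#' sharp_angle: 80          # degrees
#' twist_gain: 3            # mm
#' n_streamlines: 400       # per division and side
#' jitter_sd: 0.4           # mm
#' rng_seed: 42
#' lgn_left: [-24, -31, 2]  # world mm landmarks
#' lgn_right: [24, -31, 2]
#' tip_left: [-34, 25, -12]
#' tip_right: [34, 25, -12]
#' ```
#'
#' @param path YAML file path.
#' @return a [phantom_spec()].
#' @export
phantom_spec_from_config <- function(path) {
  if (!file.exists(path)) stop("no such config file: ", path)
  cfg <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(cfg$voxel_mm))
    args$grid <- default_phantom_grid(cfg$voxel_mm)
  if (!is.null(cfg$dtm_left) || !is.null(cfg$dtm_right))
    args$dtm_mm <- c(left = cfg$dtm_left %||% 23.1,
                     right = cfg$dtm_right %||% 26.41)
  if (!is.null(cfg$lgn_left) || !is.null(cfg$lgn_right))
    args$lgn_center <- list(left = as.numeric(cfg$lgn_left %||% c(-24, -31, 2)),
                            right = as.numeric(cfg$lgn_right %||% c(24, -31, 2)))
  if (!is.null(cfg$tip_left) || !is.null(cfg$tip_right))
    args$temporal_tip <- list(
      left = as.numeric(cfg$tip_left %||% c(-34, 25, -12)),
      right = as.numeric(cfg$tip_right %||% c(34, 25, -12)))
  for (key in c("fan_half_angle", "sharp_angle", "twist_gain",
                "n_streamlines", "jitter_sd", "rng_seed"))
    if (!is.null(cfg[[key]])) args[[key]] <- cfg[[key]]
  do.call(phantom_spec, args)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
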