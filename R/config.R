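#' Pipeline configuration
#'
#' Collects the tunables of every stage under one object, overridable
#' from a YAML file with top-level keys `laser:`, `detection:`,
#' `occlusion:` and `trajectory:` (see the schema shipped at
#' `system.file("extdata", "config-schema.yaml", package = "mfce")`).
#'
#' @param laser a [laser_detection_config()]
#' @param detection list for the classical backend: `min_diff` (intensity
#'   units), `min_area` (px^2)
#' @param occlusion an [occlusion_search_config()]
#' @param trajectory list: `stationary_speed` (px/frame), `sustain`
#'   (frames), `min_points`, `method` (`"fitted_curve"` or `"raw_series"`)
#' @param D physical inter-laser distance, mm
#' @return an `mfce_config`
#' @export
mfce_config <- function(laser = laser_detection_config(),
                        detection = list(min_diff = 40, min_area = 150),
                        occlusion = occlusion_search_config(),
                        trajectory = list(stationary_speed = 0.5,
                                          sustain = 3L, min_points = 8L,
                                          method = "fitted_curve"),
                        D = 164) {
  structure(list(laser = laser, detection = detection,
                 occlusion = occlusion, trajectory = trajectory, D = D),
            class = "mfce_config")
}

#' Read a YAML configuration
#'
#' Unknown keys raise an error so typos do not silently fall back to
#' defaults.
#'
#' @param path YAML file
#' @param base configuration to override (default [mfce_config()])
#' @return an `mfce_config`
#' @export
read_mfce_config <- function(path, base = mfce_config()) {
  y <- yaml::read_yaml(path)
  known <- c("laser", "detection", "occlusion", "trajectory", "D")
  bad <- setdiff(names(y), known)
  if (length(bad)) stop("unknown config keys: ", paste(bad, collapse = ", "))
  if (!is.null(y$laser)) {
    base$laser <- do.call(laser_detection_config,
                          utils::modifyList(unclass(base$laser), y$laser))
  }
  if (!is.null(y$detection)) {
    base$detection <- utils::modifyList(base$detection, y$detection)
  }
  if (!is.null(y$occlusion)) {
    base$occlusion <- do.call(occlusion_search_config,
                              utils::modifyList(unclass(base$occlusion), y$occlusion))
  }
  if (!is.null(y$trajectory)) {
    base$trajectory <- utils::modifyList(base$trajectory, y$trajectory)
  }
  if (!is.null(y$D)) base$D <- y$D
  base
}
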