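#' Analyze an in-memory frame sequence
#'
#' The full offline pipeline on a list of frames: per-frame segmentation
#' through the chosen backend, the four-state frame classifier, swing vs
#' stance labelling against the ground line, chamfer occlusion recovery on
#' overlap frames, laser calibration (automatic, unless a manual one is
#' supplied), stride segmentation, quintic fitting, and MFC extraction in
#' pixels and millimetres.
#'
#' @param frames list of [video_frame()] objects, ordered
#' @param ground a [ground_plane()]
#' @param backend a segmentation backend (see [segmentation_backends])
#' @param config an [mfce_config()]
#' @param calibration optional `laser_calibration` (manual fallback);
#'   when `NULL`, automatic dot detection is attempted on every frame
#'   until it succeeds
#' @param pedestrian_id identifier for the results table
#' @return list with `estimates` (per-stride data frame), `track`,
#'   `strides`, `states`, `direction`, `calibration`, `flags` (character
#'   vector: `"incomplete_calibration"`, `"no_mfc"`)
#' @export
analyze_frames <- function(frames, ground, backend, config = mfce_config(),
                           calibration = NULL, pedestrian_id = "pedestrian") {
  state <- "NO_ONE"
  states <- character(length(frames))
  prev_swing <- NULL
  prev_centroids <- NULL
  swing_velocity <- c(0, 0)   # constant-velocity prediction for recovery
  first_det <- NULL
  cal <- calibration
  tf <- integer(0); td <- numeric(0); tc <- numeric(0); tp <- character(0)

  for (i in seq_along(frames)) {
    fr <- frames[[i]]
    masks <- segment_footwear(fr, backend)
    state <- classify_frame_state(state, length(masks))
    states[i] <- state
    if (is.null(cal)) {
      cal <- detect_laser_dots(fr, config$laser, D = config$D)
    }
    if (state == "FULLY_VISIBLE") {
      lab <- assign_swing_stance(masks, ground, prev_centroids)
      if (lab[[1]]$role == "swing") {
        swing <- lab[[1]]
        if (is.null(first_det)) first_det <- swing
        d <- suppressWarnings(lowest_point_clearance(swing, ground)$d)
        tf <- c(tf, fr$index); td <- c(td, d)
        tc <- c(tc, mask_centroid(swing)["col"]); tp <- c(tp, swing$provenance)
        ctr <- mask_centroid(swing)
        if (!is.null(prev_centroids)) {
          swing_velocity <- unname(ctr - prev_centroids$swing)
        }
        prev_swing <- swing
        prev_centroids <- list(swing = ctr, stance = mask_centroid(lab[[2]]))
      }
    } else if (state == "OVERLAP" && !is.null(prev_swing)) {
      rec <- recover_occluded_swing(prev_swing, fr, config$occlusion,
                                    predicted_shift = swing_velocity)
      d <- suppressWarnings(lowest_point_clearance(rec, ground)$d)
      tf <- c(tf, fr$index); td <- c(td, d)
      tc <- c(tc, mask_centroid(rec)["col"]); tp <- c(tp, rec$provenance)
      ctr <- mask_centroid(rec)
      if (!is.null(prev_centroids)) {
        swing_velocity <- unname(ctr - prev_centroids$swing)
        prev_centroids$swing <- ctr
      }
      prev_swing <- rec
    } else if (state == "BEGIN" && is.null(first_det) && length(masks) >= 1L) {
      first_det <- masks[[1]]
    }
  }

  flags <- character(0)
  if (is.null(cal)) flags <- c(flags, "incomplete_calibration")
  if (length(tf) < 2L) {
    return(list(estimates = data.frame(), track = NULL, strides = list(),
                states = states, direction = NA_character_,
                calibration = cal, flags = c(flags, "no_mfc")))
  }
  track <- stride_track(tf, pmax(td, 0), tc, tp)
  direction <- infer_walking_direction(first_det, frames[[1]]$width)
  tcfg <- config$trajectory
  strides <- segment_strides(track, direction,
                             stationary_speed = tcfg$stationary_speed,
                             sustain = tcfg$sustain,
                             min_points = tcfg$min_points)
  strides <- lapply(strides, function(s) {
    tryCatch(fit_quintic_trajectory(s), error = function(e) {
      message("dropping stride: ", conditionMessage(e)); NULL
    })
  })
  strides <- Filter(Negate(is.null), strides)
  res <- estimate_pedestrian_mfc(strides, cal, pedestrian_id,
                                 method = tcfg$method)
  if (nrow(res$estimates) == 0L) flags <- c(flags, "no_mfc")
  list(estimates = res$estimates, track = track, strides = strides,
       states = states, direction = direction, calibration = cal,
       flags = flags, mfc_min_mm = res$mfc_min_mm,
       mfc_mean_mm = res$mfc_mean_mm)
}

#' Analyze a video clip from disk
#'
#' Thin orchestration over [analyze_frames()]: reads a PNG frame sequence,
#' builds the requested backend, runs the pipeline, and writes
#' `results.csv` (one row per stride), `summary.json` and `run.log` to
#' `out_dir`. The two manual steps of the workflow — cropping the clip to
#' one pedestrian and clicking the two ground-plane points — are inputs
#' here.
#'
#' @param input directory of `frame_*.png` files
#' @param ground_points numeric `c(c1, r1, c2, r2)`: the two clicked
#'   ground-plane points
#' @param out_dir output directory (created)
#' @param backend `"classic"` (background subtraction against the first
#'   frame), `"masks:<dir>"` (external per-frame mask PNGs), or a
#'   `segmentation_backend` object
#' @param config an [mfce_config()] or path to a YAML config
#' @param calibration optional manual `laser_calibration`
#' @param pedestrian_id identifier for the results
#' @return invisibly, a list with `status` (0 = success, 2 = unreadable
#'   input, 3 = invalid ground plane, 4 = no MFC estimable), the
#'   `results` data frame and the `summary` list
#' @export
analyze_video <- function(input, ground_points, out_dir,
                          backend = "classic", config = mfce_config(),
                          calibration = NULL, pedestrian_id = "pedestrian") {
  if (is.character(config)) config <- read_mfce_config(config)
  frames <- tryCatch(read_frame_sequence(input), error = function(e) e)
  if (inherits(frames, "error")) {
    return(invisible(list(status = 2L, message = conditionMessage(frames))))
  }
  gp <- tryCatch(ground_plane(ground_points[1:2], ground_points[3:4]),
                 error = function(e) e)
  if (inherits(gp, "error")) {
    return(invisible(list(status = 3L, message = conditionMessage(gp))))
  }
  if (is.character(backend)) {
    if (backend == "classic") {
      backend <- classic_backend(frames[[1]],
                                 min_diff = config$detection$min_diff,
                                 min_area = config$detection$min_area)
    } else if (startsWith(backend, "masks:")) {
      backend <- mask_dir_backend(sub("^masks:", "", backend))
    } else {
      stop("unknown backend spec: ", backend)
    }
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  log_path <- file.path(out_dir, "run.log")
  res <- withCallingHandlers(
    analyze_frames(frames, gp, backend, config, calibration, pedestrian_id),
    message = function(m) {
      cat(conditionMessage(m), file = log_path, append = TRUE)
      invokeRestart("muffleMessage")
    },
    warning = function(w) {
      cat("warning: ", conditionMessage(w), "\n", file = log_path, append = TRUE)
      invokeRestart("muffleWarning")
    })

  est <- res$estimates
  out <- if (nrow(est) > 0) {
    data.frame(pedestrian_id = est$pedestrian_id,
               stride_index = est$stride_index,
               mfc_frame = est$frame_index,
               d_px = est$d_px,
               k_mm_per_px = est$k_used,
               mfc_mm = est$mfc_mm,
               method = est$method,
               fit_residual_rms = est$fit_residual_rms,
               n_points = est$n_points,
               flags = paste(res$flags, collapse = ";"))
  } else {
    data.frame(pedestrian_id = character(0), stride_index = integer(0),
               mfc_frame = integer(0), d_px = numeric(0),
               k_mm_per_px = numeric(0), mfc_mm = numeric(0),
               method = character(0), fit_residual_rms = numeric(0),
               n_points = integer(0), flags = character(0))
  }
  utils::write.csv(out, file.path(out_dir, "results.csv"), row.names = FALSE)
  summary <- list(pedestrian_id = pedestrian_id,
                  n_frames = length(frames),
                  direction = res$direction,
                  n_strides = length(res$strides),
                  calibration = if (!is.null(res$calibration)) {
                    jsonlite::fromJSON(calibration_to_json(res$calibration))
                  },
                  mfc_min_mm = res$mfc_min_mm,
                  mfc_mean_mm = res$mfc_mean_mm,
                  flags = res$flags)
  writeLines(jsonlite::toJSON(summary, auto_unbox = TRUE, digits = NA,
                              null = "null", pretty = TRUE),
             file.path(out_dir, "summary.json"))
  status <- if ("no_mfc" %in% res$flags) 4L else 0L
  invisible(list(status = status, results = out, summary = summary,
                 analysis = res))
}
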