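#' Swing-foot track and stride handling
#'
#' The pipeline stores, for every frame where the swing foot is known, a
#' *stride point*: the frame index, the swing foot's pixel clearance above
#' the ground line, the swing-mask centroid column, and the provenance of
#' the mask it came from. [stride_track()] builds the container;
#' [segment_strides()] cuts it into strides at reversals or sustained
#' stationarity of the horizontal motion.
#'
#' @param frame_index integer vector of frame indices (ordered)
#' @param clearance_px non-negative pixel clearances
#' @param centroid_col swing-mask centroid columns
#' @param provenance character vector of mask provenances
#' @return a `stride_track` data frame
#' @export
stride_track <- function(frame_index, clearance_px, centroid_col,
                         provenance = "backend") {
  stopifnot(all(clearance_px >= 0), !is.unsorted(frame_index))
  structure(
    data.frame(frame_index = as.integer(frame_index),
               clearance_px = clearance_px,
               centroid_col = centroid_col,
               provenance = rep_len(provenance, length(frame_index))),
    class = c("stride_track", "data.frame"))
}

#' Infer walking direction from the first detection
#'
#' The side of the image on which a pedestrian's shoe first appears gives
#' the walking direction: a first detection in the left half means
#' left-to-right. A centroid exactly on the midline resolves to
#' right-to-left by convention (logged).
#'
#' @param first_detection the first detected `footwear_mask` of the
#'   pedestrian's sequence
#' @param frame_width image width, px
#' @return `"left_to_right"` or `"right_to_left"`
#' @export
infer_walking_direction <- function(first_detection, frame_width) {
  col <- mask_centroid(first_detection)["col"]
  if (col == frame_width / 2) {
    message("first detection exactly at midline; using right_to_left by convention")
    return("right_to_left")
  }
  if (col < frame_width / 2) "left_to_right" else "right_to_left"
}

#' Cut a swing-foot track into strides
#'
#' The swing foot's horizontal velocity (first difference of the centroid
#' column, median-smoothed over 3 frames) signals stride boundaries: a
#' reversal against the walking direction, or speed below the stationarity
#' threshold, sustained for at least `sustain` frames, ends the stride
#' (the foot has entered stance). Runs of forward motion shorter than
#' `min_points` are discarded with a message, since a quintic cannot be
#' supported on them. A monotone track yields a single stride.
#'
#' @param track a [stride_track()]
#' @param direction `"left_to_right"` or `"right_to_left"`
#' @param stationary_speed speed below which the foot counts as stationary,
#'   px/frame (default 0.5)
#' @param sustain frames of stationarity/reversal needed to cut (default 3)
#' @param min_points minimum points per stride (default 8: six quintic
#'   unknowns plus slack)
#' @return list of `stride` objects, each with `points` (the track subset),
#'   `direction`, and empty fit slots
#' @export
segment_strides <- function(track, direction = "left_to_right",
                            stationary_speed = 0.5, sustain = 3L,
                            min_points = 8L) {
  n <- nrow(track)
  if (n < 2L) stop("need at least 2 track points")
  s <- if (direction == "left_to_right") 1 else -1
  v <- diff(track$centroid_col) * s
  v <- if (length(v) >= 3L) stats::runmed(v, 3L, endrule = "keep") else v
  # per-point forward-motion flag: a point moves if either adjacent
  # velocity sample is at or above the stationarity threshold
  vpt <- pmax(c(v, -Inf), c(-Inf, v))
  moving <- vpt >= stationary_speed
  # tolerate brief dips: only runs of >= `sustain` non-moving points cut
  r <- rle(moving)
  cut <- !r$values & r$lengths >= sustain
  grp <- integer(n); gid <- 0L; pos <- 0L; in_cut_prev <- TRUE
  for (i in seq_along(r$lengths)) {
    idx <- pos + seq_len(r$lengths[i]); pos <- pos + r$lengths[i]
    if (cut[i]) {
      grp[idx] <- 0L
      in_cut_prev <- TRUE
    } else {
      if (in_cut_prev) gid <- gid + 1L
      grp[idx] <- gid
      in_cut_prev <- FALSE
    }
  }
  strides <- list()
  for (g in setdiff(unique(grp), 0L)) {
    pts <- track[grp == g, , drop = FALSE]
    if (nrow(pts) < min_points) {
      message(sprintf("discarding %d-point partial stride (< %d points)",
                      nrow(pts), min_points))
      next
    }
    strides[[length(strides) + 1L]] <-
      structure(list(points = pts, direction = direction,
                     coefficients = NULL, coefficients_scaled = NULL,
                     fit_residual_rms = NA_real_),
                class = "stride")
  }
  strides
}

#' @export
print.stride <- function(x, ...) {
  cat(sprintf("<stride  %d points  frames %d-%d  direction %s  fit rms %s>\n",
              nrow(x$points), min(x$points$frame_index), max(x$points$frame_index),
              x$direction,
              if (is.na(x$fit_residual_rms)) "unfitted" else
                sprintf("%.3f px", x$fit_residual_rms)))
  invisible(x)
}

#' Fit a quintic to a stride's clearance trajectory
#'
#' Least-squares fit of clearance (px) against frame index, degree 5. The
#' swing-foot height profile of one stride has three inflection points,
#' which a quintic is the lowest-degree polynomial able to represent. For
#' conditioning, abscissae are affinely mapped to \[-1, 1\] before the
#' normal equations are solved; coefficients are reported both in that
#' scaled basis and mapped back to the original frame-index basis. Every
#' fit checks that its second derivative (a cubic) has at most 3 real
#' roots, i.e. at most 3 inflection points.
#'
#' @param stride a `stride` from [segment_strides()]
#' @return the stride with `coefficients` (frame-index basis, ascending
#'   a0..a5), `coefficients_scaled` (basis on \[-1, 1\]), `fit_residual_rms`
#'   (px), and `abscissa_map = c(center, halfwidth)` filled in
#' @export
fit_quintic_trajectory <- function(stride) {
  pts <- stride$points
  n <- nrow(pts)
  if (n < 8L) stop("insufficient support: a quintic fit needs at least 8 points")
  t <- pts$frame_index
  if (length(unique(t)) < 6L) stop("insufficient support: fewer than 6 distinct abscissae")
  m <- (max(t) + min(t)) / 2
  s <- (max(t) - min(t)) / 2
  u <- (t - m) / s
  X <- outer(u, 0:5, `^`)
  fit <- stats::lm.fit(X, pts$clearance_px)
  b <- fit$coefficients
  b[is.na(b)] <- 0
  resid <- pts$clearance_px - drop(X %*% b)
  # map back: h(t) = sum b_j ((t - m)/s)^j
  coef_t <- poly_affine_subst(b, -m / s, 1 / s)
  # inflection count: real roots of the (cubic) second derivative
  d2 <- poly_deriv(poly_deriv(b))
  stopifnot(length(poly_real_roots(d2)) <= 3L)
  stride$coefficients <- coef_t
  stride$coefficients_scaled <- unname(b)
  stride$abscissa_map <- c(center = m, halfwidth = s)
  stride$fit_residual_rms <- sqrt(mean(resid^2))
  stride
}

#' Locate the minimum-foot-clearance point of a stride
#'
#' Two methods:
#' * `"fitted_curve"` (default): real roots of the fitted quintic's
#'   derivative strictly inside the stride interval with positive second
#'   derivative are local minima; the quintic is evaluated there, clipped
#'   at zero, and the lowest minimum wins. Deterministic and sub-frame
#'   accurate.
#' * `"raw_series"`: the smallest interior clearance sample that is less
#'   than or equal to both neighbours.
#'
#' Stride endpoints are never MFC candidates: a boundary minimum means the
#' true MFC may lie outside the field of view, and such strides yield no
#' estimate (logged, not an error).
#'
#' @param stride a fitted `stride`
#' @param method `"fitted_curve"` or `"raw_series"`
#' @return an `mfc_estimate` list with `frame_index` (nearest integer
#'   frame), `d_px`, and `method`; or `NULL` when the stride has no
#'   interior local minimum
#' @export
locate_mfc <- function(stride, method = c("fitted_curve", "raw_series")) {
  method <- match.arg(method)
  pts <- stride$points
  f0 <- min(pts$frame_index); f1 <- max(pts$frame_index)
  if (method == "raw_series") {
    y <- pts$clearance_px
    n <- length(y)
    ii <- which(y[2:(n - 1)] <= y[1:(n - 2)] & y[2:(n - 1)] <= y[3:n]) + 1L
    if (length(ii) == 0L) {
      message("no interior raw-series minimum; stride yields no MFC")
      return(NULL)
    }
    i <- ii[which.min(y[ii])]
    return(structure(list(frame_index = pts$frame_index[i],
                          d_px = max(0, y[i]), method = "raw_series"),
                     class = "mfc_estimate"))
  }
  if (is.null(stride$coefficients_scaled)) stop("stride is not fitted")
  b <- stride$coefficients_scaled
  m <- stride$abscissa_map["center"]; s <- stride$abscissa_map["halfwidth"]
  db <- poly_deriv(b); d2b <- poly_deriv(db)
  roots_u <- poly_real_roots(db)
  u0 <- (f0 - m) / s; u1 <- (f1 - m) / s
  cand <- roots_u[roots_u > u0 + 1e-9 & roots_u < u1 - 1e-9]
  cand <- cand[poly_eval(d2b, cand) > 0]
  if (length(cand) == 0L) {
    message("fitted curve has no interior local minimum; stride yields no MFC")
    return(NULL)
  }
  vals <- pmax(0, poly_eval(b, cand))
  i <- which.min(vals)
  frame <- round(m + s * cand[i])
  frame <- min(max(frame, f0 + 1), f1 - 1)  # keep the reported frame interior
  structure(list(frame_index = as.integer(frame), d_px = vals[i],
                 method = "fitted_curve"),
            class = "mfc_estimate")
}

#' Per-pedestrian MFC estimates in millimetres
#'
#' Applies [locate_mfc()] to each fitted stride and converts pixel
#' clearances to millimetres with the pedestrian's laser calibration
#' (`MFC = d * k`). Without a calibration the estimates are emitted in
#' pixels only and the result is flagged incomplete.
#'
#' @param strides list of fitted `stride` objects
#' @param calibration a `laser_calibration`, or `NULL` when neither
#'   automatic detection nor manual annotation produced one
#' @param pedestrian_id identifier carried into the results
#' @param method MFC extraction method, see [locate_mfc()]
#' @return list with `estimates` (data frame: pedestrian_id, stride_index,
#'   frame_index, d_px, k_used, mfc_mm, method), `mfc_min_mm`,
#'   `mfc_mean_mm` (NA without calibration), and `calibrated` flag
#' @export
estimate_pedestrian_mfc <- function(strides, calibration = NULL,
                                    pedestrian_id = "pedestrian",
                                    method = "fitted_curve") {
  rows <- list()
  for (i in seq_along(strides)) {
    est <- locate_mfc(strides[[i]], method = method)
    if (is.null(est)) next
    k <- if (!is.null(calibration)) calibration$k else NA_real_
    rows[[length(rows) + 1L]] <- data.frame(
      pedestrian_id = pedestrian_id, stride_index = i,
      frame_index = est$frame_index, d_px = est$d_px,
      k_used = k,
      mfc_mm = if (!is.null(calibration)) clearance_to_mm(est$d_px, k) else NA_real_,
      method = est$method,
      fit_residual_rms = strides[[i]]$fit_residual_rms,
      n_points = nrow(strides[[i]]$points))
  }
  est <- if (length(rows)) do.call(rbind, rows) else data.frame()
  list(estimates = est,
       mfc_min_mm = if (length(rows) && !is.null(calibration)) min(est$mfc_mm) else NA_real_,
       mfc_mean_mm = if (length(rows) && !is.null(calibration)) mean(est$mfc_mm) else NA_real_,
       calibrated = !is.null(calibration))
}
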