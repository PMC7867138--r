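#' Occlusion search configuration
#'
#' When the two feet overlap, the swing foot is re-localized by matching
#' the previous frame's swing bottom edge against the current frame's
#' edge map over a small grid of rotations and integer translations. The
#' rotation grid spans +/-20 degrees in 5-degree steps (9 candidates);
#' the translation window defaults to +/-40 columns and +/-15 rows, sized
#' to inter-frame foot motion at 60 fps.
#'
#' @param rotation_range_deg half-range of the rotation search, degrees
#'   (default 20)
#' @param rotation_step_deg rotation step, degrees (default 5); must
#'   divide the range
#' @param translation_window_px `c(cols, rows)` half-window of the integer
#'   translation search (default `c(40, 15)`)
#' @param motion_penalty weight of the motion-prior regularizer, in
#'   distance-transform pixels of score per pixel of deviation from the
#'   predicted displacement (default 0.02). When the stance shoe presents
#'   a near-identical copy of the swing sole, raw chamfer scores can tie
#'   or invert under noise; the small penalty makes the placement
#'   consistent with the observed foot motion win without influencing
#'   clear matches
#' @param edge_gradient_threshold threshold on the gradient-magnitude
#'   image defining edge pixels, in intensity units per pixel. The default
#'   10 keeps genuine low-contrast boundaries — in particular the edge
#'   between two overlapping shoes of similar darkness, which is exactly
#'   what the recovery must latch onto — while staying above sensor-noise
#'   gradients. `NULL` selects the threshold per frame by Otsu's method on
#'   the gradient magnitudes, which is adaptive but tends to discard
#'   instance boundaries much weaker than the silhouette-background edges
#' @return an `occlusion_search_config`
#' @export
occlusion_search_config <- function(rotation_range_deg = 20,
                                    rotation_step_deg = 5,
                                    translation_window_px = c(40, 15),
                                    edge_gradient_threshold = 10,
                                    motion_penalty = 0.02) {
  stopifnot(rotation_range_deg > 0, rotation_step_deg > 0,
            all(translation_window_px > 0), motion_penalty >= 0)
  if (abs(rotation_range_deg / rotation_step_deg -
          round(rotation_range_deg / rotation_step_deg)) > 1e-9) {
    stop("rotation_step_deg must divide rotation_range_deg")
  }
  structure(list(rotation_range_deg = rotation_range_deg,
                 rotation_step_deg = rotation_step_deg,
                 translation_window_px = as.integer(translation_window_px),
                 edge_gradient_threshold = edge_gradient_threshold,
                 motion_penalty = motion_penalty),
            class = "occlusion_search_config")
}

#' Edge map of a frame
#'
#' Gradient magnitude by central differences, thresholded into a binary
#' edge mask. Central differences respond on both sides of a step, which
#' would make every silhouette boundary a two-pixel band and leave the
#' sole template one pixel of vertical ambiguity; the map therefore keeps
#' only the dark-side pixel of each strong gradient (intensity below the
#' 4-neighbourhood mean). Edge pixels then coincide with silhouette
#' boundary pixels — a mask's bottom edge is its last dark row — which is
#' the convention the occlusion template uses. With `threshold = NULL`
#' the cut is chosen per frame by Otsu's method on the normalized
#' gradient magnitudes.
#'
#' @param frame a [video_frame()]
#' @param threshold gradient-magnitude threshold on the 0–255 intensity
#'   scale, or `NULL` for Otsu
#' @return logical matrix of edge pixels
#' @export
frame_edge_map <- function(frame, threshold = NULL) {
  px <- frame$pixels
  nr <- nrow(px); nc <- ncol(px)
  gx <- matrix(0, nr, nc); gy <- matrix(0, nr, nc)
  gx[, 2:(nc - 1)] <- (px[, 3:nc] - px[, 1:(nc - 2)]) / 2
  gy[2:(nr - 1), ] <- (px[3:nr, ] - px[1:(nr - 2), ]) / 2
  mag <- sqrt(gx^2 + gy^2)
  mx <- max(mag)
  if (mx == 0) return(matrix(FALSE, nr, nc))
  if (is.null(threshold)) {
    threshold <- EBImage::otsu(mag / mx, range = c(0, 1)) * mx
  }
  # dark-side thinning: keep the boundary pixel on the darker side
  up <- px[c(1, seq_len(nr - 1)), ]
  dn <- px[c(seq_len(nr - 1) + 1, nr), ]
  lf <- px[, c(1, seq_len(nc - 1))]
  rt <- px[, c(seq_len(nc - 1) + 1, nc)]
  mag > threshold & px < (up + dn + lf + rt) / 4
}

# distance transform: per-pixel Euclidean distance to the nearest edge
# pixel; pixels with no edges anywhere get a large sentinel
edge_distance_map <- function(edges) {
  if (!any(edges)) {
    return(matrix(sqrt(sum(dim(edges)^2)), nrow(edges), ncol(edges)))
  }
  EBImage::distmap(1 - edges)
}

rotate_points <- function(pts, angle_deg, center) {
  th <- angle_deg * pi / 180
  co <- cos(th); si <- sin(th)
  dc <- pts[, 1] - center[1]; dr <- pts[, 2] - center[2]
  cbind(center[1] + co * dc - si * dr, center[2] + si * dc + co * dr)
}

#' Recover the swing foot during an overlap frame
#'
#' Chamfer-style template matching: the previous swing mask's bottom-edge
#' point set is rotated about its centroid by each angle on the rotation
#' grid and shifted by each integer translation in the window; every
#' placement is scored by the mean distance-transform value of the current
#' frame's edge map at the (rounded) transformed points, lower being
#' better. The previous mask transformed by the best placement becomes the
#' recovered swing mask. Ties are resolved toward the smaller translation
#' magnitude, then the smaller absolute rotation.
#'
#' When the two shoes are near-identical, the stance shoe's sole edge is
#' an almost perfect copy of the swing template and can tie the score at
#' a wrong placement. The caller can therefore pass a constant-velocity
#' `predicted_shift`; the translation window is centred on it and ties
#' resolve toward the prediction, which disambiguates the copies without
#' affecting the no-history case (prediction zero).
#'
#' @param prev_swing the swing `footwear_mask` from the previous frame
#' @param frame the current (overlap) [video_frame()]
#' @param config an [occlusion_search_config()]
#' @param predicted_shift expected swing-foot displacement since the
#'   previous frame, `c(cols, rows)` (default `c(0, 0)`)
#' @return the recovered `footwear_mask` (`provenance =
#'   "occlusion_recovery"`) with attributes `rotation_deg`,
#'   `translation_px` (total `c(cols, rows)`, prediction included),
#'   `score`, and `low_confidence` set when the frame contains no edges
#'   to match against
#' @export
recover_occluded_swing <- function(prev_swing, frame,
                                   config = occlusion_search_config(),
                                   predicted_shift = c(0, 0)) {
  edges <- frame_edge_map(frame, config$edge_gradient_threshold)
  be <- prev_swing$bottom_edge
  if (!any(edges)) {
    out <- prev_swing
    out$provenance <- "occlusion_recovery"
    attr(out, "rotation_deg") <- 0
    attr(out, "translation_px") <- c(0L, 0L)
    attr(out, "score") <- NA_real_
    attr(out, "low_confidence") <- TRUE
    return(out)
  }
  dt <- edge_distance_map(edges)
  nr <- nrow(dt); nc <- ncol(dt)
  win <- config$translation_window_px
  # pad the distance map so translated lookups never leave the grid;
  # out-of-frame placements score the sentinel (worst plausible) value
  pad <- max(win) + 60L
  sentinel <- max(dt) + 1
  dtp <- matrix(sentinel, nr + 2L * pad, nc + 2L * pad)
  dtp[pad + seq_len(nr), pad + seq_len(nc)] <- dt
  nrp <- nrow(dtp)

  angles <- seq(-config$rotation_range_deg, config$rotation_range_deg,
                by = config$rotation_step_deg)
  pred <- round(predicted_shift)
  dcs <- pred[1] + seq(-win[1], win[1]); drs <- pred[2] + seq(-win[2], win[2])
  # translation offsets as linear-index offsets into the padded map
  shift_grid <- expand.grid(dc = dcs, dr = drs)
  lin_shift <- shift_grid$dc * nrp + shift_grid$dr
  # tie-breaks measured as deviation from the predicted motion
  trans_mag <- sqrt((shift_grid$dc - pred[1])^2 + (shift_grid$dr - pred[2])^2)

  centroid <- colMeans(be)
  best <- NULL
  for (a in angles) {
    rp <- rotate_points(be, a, centroid)
    rc <- round(rp[, 1]) + pad; rr <- round(rp[, 2]) + pad
    lin0 <- (rc - 1) * nrp + rr
    # score all translations at once: offsets are exact in the padded map
    scores <- colMeans(matrix(dtp[rep(lin0, times = length(lin_shift)) +
                                    rep(lin_shift, each = length(lin0))],
                              nrow = length(lin0)))
    sel <- scores + config$motion_penalty * trans_mag
    i <- order(sel, trans_mag,
               abs(shift_grid$dc - pred[1]) + abs(shift_grid$dr - pred[2]))[1]
    cand <- list(score = sel[i], raw_score = scores[i], angle = a,
                 dc = shift_grid$dc[i], dr = shift_grid$dr[i],
                 mag = trans_mag[i])
    if (is.null(best) ||
        cand$score < best$score - 1e-12 ||
        (abs(cand$score - best$score) <= 1e-12 &&
         (cand$mag < best$mag - 1e-12 ||
          (abs(cand$mag - best$mag) <= 1e-12 && abs(cand$angle) < abs(best$angle))))) {
      best <- cand
    }
  }
  out <- transform_mask(prev_swing, best$angle, c(best$dc, best$dr), centroid)
  out$frame_index <- frame$index
  out$role <- "swing"
  out$provenance <- "occlusion_recovery"
  attr(out, "rotation_deg") <- best$angle
  attr(out, "translation_px") <- c(best$dc, best$dr)
  attr(out, "score") <- best$raw_score
  attr(out, "low_confidence") <- FALSE
  out
}

# rigidly transform a mask: rotate by angle_deg about `center`
# (column, row), then translate by `shift` = c(dcols, drows).
# Nearest-neighbour inverse mapping over the transformed bounding box.
transform_mask <- function(mask, angle_deg, shift, center) {
  if (angle_deg == 0) {
    bbox <- mask$bbox + as.integer(c(shift[1], shift[2], shift[1], shift[2]))
    return(footwear_mask(mask$submask, frame_index = mask$frame_index,
                         role = mask$role, shape = mask$shape, bbox = bbox))
  }
  corners <- cbind(mask$bbox[c(1, 3, 1, 3)], mask$bbox[c(2, 2, 4, 4)])
  rc <- rotate_points(corners, angle_deg, center)
  c0 <- floor(min(rc[, 1])) + shift[1]; c1 <- ceiling(max(rc[, 1])) + shift[1]
  r0 <- floor(min(rc[, 2])) + shift[2]; r1 <- ceiling(max(rc[, 2])) + shift[2]
  cols <- c0:c1; rows <- r0:r1
  grid <- cbind(rep(cols, each = length(rows)), rep(rows, times = length(cols)))
  # invert: undo translation, rotate back
  src <- rotate_points(cbind(grid[, 1] - shift[1], grid[, 2] - shift[2]),
                       -angle_deg, center)
  sc <- round(src[, 1]); sr <- round(src[, 2])
  inside <- sc >= mask$bbox[1] & sc <= mask$bbox[3] &
    sr >= mask$bbox[2] & sr <= mask$bbox[4]
  val <- logical(nrow(grid))
  val[inside] <- mask$submask[cbind(sr[inside] - mask$bbox[2] + 1L,
                                    sc[inside] - mask$bbox[1] + 1L)]
  sub <- matrix(val, nrow = length(rows), ncol = length(cols))
  footwear_mask(sub, frame_index = mask$frame_index, role = mask$role,
                shape = mask$shape, bbox = c(c0, r0, c1, r1))
}
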