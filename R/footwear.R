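#' Footwear instance masks
#'
#' A `footwear_mask` is a binary instance mask aligned to a video frame,
#' with a role label (swing / stance / unknown), a tight bounding box, its
#' bottom-edge profile (the maximal occupied row in each occupied column),
#' and a provenance tag saying whether it came from a segmentation backend,
#' from occlusion recovery, or from synthetic ground truth. Masks are
#' stored compactly as the logical sub-grid inside the bounding box so that
#' full-HD sequences stay cheap to hold in memory.
#'
#' @param mask full-frame logical matrix (`[row, column]`), or the sub-grid
#'   inside `bbox` when `bbox` is supplied
#' @param frame_index frame the mask belongs to
#' @param role one of `"swing"`, `"stance"`, `"unknown"`
#' @param provenance one of `"backend"`, `"occlusion_recovery"`, `"oracle"`
#' @param shape frame dimensions `c(height, width)`; required with `bbox`
#' @param bbox `c(min_col, min_row, max_col, max_row)` when `mask` is a
#'   sub-grid
#' @return a `footwear_mask` object
#' @export
footwear_mask <- function(mask, frame_index = 0L,
                          role = c("unknown", "swing", "stance"),
                          provenance = c("backend", "occlusion_recovery", "oracle"),
                          shape = NULL, bbox = NULL) {
  role <- match.arg(role)
  provenance <- match.arg(provenance)
  if (is.null(bbox)) {
    stopifnot(is.matrix(mask))
    shape <- dim(mask)
    occ <- which(mask, arr.ind = TRUE)
    if (nrow(occ) == 0L) stop("footwear mask is empty")
    bbox <- c(min(occ[, 2]), min(occ[, 1]), max(occ[, 2]), max(occ[, 1]))
    sub <- mask[bbox[2]:bbox[4], bbox[1]:bbox[3], drop = FALSE]
  } else {
    stopifnot(!is.null(shape), is.matrix(mask))
    sub <- mask
    if (!any(sub)) stop("footwear mask is empty")
    # tighten the bbox if the sub-grid has empty margins
    occ <- which(sub, arr.ind = TRUE)
    r0 <- min(occ[, 1]); r1 <- max(occ[, 1])
    c0 <- min(occ[, 2]); c1 <- max(occ[, 2])
    sub <- sub[r0:r1, c0:c1, drop = FALSE]
    bbox <- c(bbox[1] + c0 - 1L, bbox[2] + r0 - 1L,
              bbox[1] + c1 - 1L, bbox[2] + r1 - 1L)
  }
  be <- bottom_edge_of(sub, bbox)
  structure(
    list(frame_index = as.integer(frame_index), shape = as.integer(shape),
         bbox = as.integer(bbox), submask = sub, bottom_edge = be,
         role = role, provenance = provenance),
    class = "footwear_mask")
}

# bottom edge: for each occupied column, the maximal occupied row
bottom_edge_of <- function(sub, bbox) {
  cols <- which(colSums(sub) > 0)
  rows <- vapply(cols, function(j) max(which(sub[, j])), integer(1))
  cbind(col = bbox[1] + cols - 1L, row = bbox[2] + rows - 1L)
}

#' @export
print.footwear_mask <- function(x, ...) {
  cat(sprintf("<footwear_mask frame %d  role %s  provenance %s  bbox [%d,%d]-[%d,%d]  area %d px>\n",
              x$frame_index, x$role, x$provenance,
              x$bbox[1], x$bbox[2], x$bbox[3], x$bbox[4], mask_area(x)))
  invisible(x)
}

#' Expand a footwear mask to a full-frame logical matrix
#' @param m a `footwear_mask`
#' @return logical matrix of the frame's dimensions
#' @export
mask_full <- function(m) {
  full <- matrix(FALSE, m$shape[1], m$shape[2])
  full[m$bbox[2]:m$bbox[4], m$bbox[1]:m$bbox[3]] <- m$submask
  full
}

#' @rdname mask_full
#' @export
mask_area <- function(m) sum(m$submask)

#' Centroid of a footwear mask
#' @param m a `footwear_mask`
#' @return `c(col, row)` centroid of the mask pixels
#' @export
mask_centroid <- function(m) {
  occ <- which(m$submask, arr.ind = TRUE)
  c(col = m$bbox[1] - 1 + mean(occ[, 2]), row = m$bbox[2] - 1 + mean(occ[, 1]))
}

#' Frame-state machine for occlusion tracking
#'
#' Each frame is categorized by how many footwear masks the backend found,
#' conditioned on the previous state: `NO_ONE` (empty walkway), `BEGIN`
#' (a pedestrian has just entered, one foot visible), `FULLY_VISIBLE`
#' (both feet visible and separable), `OVERLAP` (the two feet overlap in
#' the sagittal plane and are not separable). The transition from
#' `FULLY_VISIBLE` on a single mask raises the occlusion flag that triggers
#' swing-foot recovery. The table is total and deterministic:
#'
#' | previous       | 0 masks | 1 mask  | 2 masks       |
#' |----------------|---------|---------|---------------|
#' | NO_ONE         | NO_ONE  | BEGIN   | FULLY_VISIBLE |
#' | BEGIN          | NO_ONE  | BEGIN   | FULLY_VISIBLE |
#' | FULLY_VISIBLE  | NO_ONE  | OVERLAP | FULLY_VISIBLE |
#' | OVERLAP        | NO_ONE  | OVERLAP | FULLY_VISIBLE |
#'
#' @param previous previous state, one of `"NO_ONE"`, `"BEGIN"`,
#'   `"FULLY_VISIBLE"`, `"OVERLAP"`
#' @param n_masks number of masks found in the current frame (0, 1 or 2;
#'   more than 2 keeps the previous state with a warning, since
#'   multi-pedestrian scenes are out of scope)
#' @return the new state
#' @export
classify_frame_state <- function(previous, n_masks) {
  states <- c("NO_ONE", "BEGIN", "FULLY_VISIBLE", "OVERLAP")
  previous <- match.arg(previous, states)
  if (n_masks > 2) {
    warning("more than 2 footwear masks in frame; keeping previous state")
    return(previous)
  }
  if (n_masks == 0) return("NO_ONE")
  if (n_masks == 2) return("FULLY_VISIBLE")
  # exactly one mask
  switch(previous,
         NO_ONE = "BEGIN",
         BEGIN = "BEGIN",
         FULLY_VISIBLE = "OVERLAP",
         OVERLAP = "OVERLAP")
}

#' Label swing and stance feet
#'
#' Of two visible feet, the one further from the walkway is airborne: the
#' mask whose lowest point has the greater vertical distance to the ground
#' line is labelled `swing`, the other `stance`. Near-ties (clearance
#' difference below 0.5 px, i.e. double support) are broken by which
#' centroid moved more since the previous frame; with no motion history
#' both masks stay `unknown`.
#'
#' @param masks list of exactly two `footwear_mask` objects
#' @param ground a [ground_plane()]
#' @param prev_centroids optional list of the previous frame's swing and
#'   stance centroids, `list(swing =, stance =)` each `c(col, row)`; used
#'   only for the tie-break
#' @return the two masks with `role` set (order: swing first)
#' @export
assign_swing_stance <- function(masks, ground, prev_centroids = NULL) {
  stopifnot(length(masks) == 2L)
  d <- vapply(masks, function(m) lowest_point_clearance(m, ground)$d, numeric(1))
  if (abs(d[1] - d[2]) >= 0.5) {
    swing_i <- which.max(d)
  } else {
    if (is.null(prev_centroids)) {
      masks[[1]]$role <- "unknown"; masks[[2]]$role <- "unknown"
      return(masks)
    }
    # the swing foot is the moving one: larger displacement since last frame
    ref <- rbind(prev_centroids$swing, prev_centroids$stance)
    disp <- vapply(masks, function(m) {
      min(sqrt(rowSums((ref - matrix(mask_centroid(m), nrow(ref), 2, byrow = TRUE))^2)))
    }, numeric(1))
    # displacement to its nearest previous track; larger mover is swing
    swing_i <- which.max(disp)
  }
  masks[[swing_i]]$role <- "swing"
  masks[[-swing_i + 3L]]$role <- "stance"
  masks[c(swing_i, -swing_i + 3L)]
}

#' Clearance of a mask's lowest point above the ground line
#'
#' For every bottom-edge point the vertical distance to the ground line is
#' `ground_row_at(column) - row`; the minimum over columns is the pixel
#' clearance `d` used in the MFC computation. Points that fall below the
#' ground line (negative distance) are clipped to zero and flagged.
#'
#' @param mask a `footwear_mask`
#' @param ground a [ground_plane()]
#' @return list with `d` (pixels, >= 0), `point` (`c(col, row)` achieving
#'   it) and `below_ground` flag
#' @export
lowest_point_clearance <- function(mask, ground) {
  be <- mask$bottom_edge
  dist <- ground_row_at(ground, be[, "col"]) - be[, "row"]
  i <- which.min(dist)
  d <- dist[i]
  below <- d < 0
  if (below) {
    warning("footwear mask extends below the ground line; clearance clipped to 0")
    d <- 0
  }
  list(d = unname(d),
       point = c(col = unname(be[i, "col"]), row = unname(be[i, "row"])),
       below_ground = below)
}
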