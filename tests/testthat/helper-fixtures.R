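# Shared fixtures and independent brute-force oracles.
# Every fixture is built in code under a fixed seed; nothing is read from
# disk except what a test itself writes to a tempdir.

# frame containing filled discs (and optionally a streak) on a graded
# background; centers are (col, row)
disc_frame <- function(height, width, centers, radius = 5,
                       intensity = 255, bg = 100, streak = NULL,
                       streak_intensity = 255, index = 0L) {
  cols <- matrix(seq_len(width), height, width, byrow = TRUE)
  rows <- matrix(seq_len(height), height, width)
  px <- matrix(bg, height, width) + 20 * (cols / width)  # bg stays <= ~120
  for (ct in centers) {
    d2 <- (cols - ct[1])^2 + (rows - ct[2])^2
    px[d2 <= radius^2] <- intensity
  }
  if (!is.null(streak)) {
    # streak = list(col0, row0, length_cols, half_rows)
    sel <- cols >= streak[1] & cols < streak[1] + streak[3] &
      abs(rows - streak[2]) <= streak[4]
    px[sel] <- streak_intensity
  }
  video_frame(pmin(px, 255), index = index)
}

# brute-force bottom edge: per-column scan of a full logical matrix
bf_bottom_edge <- function(full) {
  cols <- which(apply(full, 2, any))
  cbind(col = cols,
        row = vapply(cols, function(j) max(which(full[, j])), integer(1)))
}

# brute-force IOU by explicit pixel loop
bf_iou <- function(a, b) {
  inter <- 0L; union <- 0L
  for (i in seq_len(nrow(a))) {
    for (j in seq_len(ncol(a))) {
      if (a[i, j] && b[i, j]) inter <- inter + 1L
      if (a[i, j] || b[i, j]) union <- union + 1L
    }
  }
  if (union == 0L) return(1)
  inter / union
}

# brute-force bottom-edge RMS over shared columns
bf_bottom_rms <- function(full_a, full_b) {
  ea <- bf_bottom_edge(full_a); eb <- bf_bottom_edge(full_b)
  shared <- intersect(ea[, "col"], eb[, "col"])
  if (length(shared) == 0L) return(NA_real_)
  sq <- 0
  for (cc in shared) {
    ra <- ea[ea[, "col"] == cc, "row"]; rb <- eb[eb[, "col"] == cc, "row"]
    sq <- sq + (ra - rb)^2
  }
  unname(sqrt(sq / length(shared)))
}

# random blobby mask: union of a few random rectangles
random_mask <- function(seed, height = 30, width = 40, n_rect = 3) {
  withr::with_seed(seed, {
    m <- matrix(FALSE, height, width)
    for (i in seq_len(n_rect)) {
      r0 <- sample(height - 5, 1); c0 <- sample(width - 5, 1)
      m[r0:(r0 + sample(5, 1)), c0:(c0 + sample(5, 1))] <- TRUE
    }
    m
  })
}

# brute-force chamfer scorer replicating the recovery's search order:
# returns the winning (angle, dc, dr) over the same grid with the same
# tie-breaks, computed with plain loops
bf_chamfer_argmin <- function(be, frame, config) {
  edges <- frame_edge_map(frame, config$edge_gradient_threshold)
  dt <- as.matrix(EBImage::distmap(1 - edges))
  nr <- nrow(dt); nc <- ncol(dt)
  sentinel <- max(dt) + 1
  centroid <- colMeans(be)
  angles <- seq(-config$rotation_range_deg, config$rotation_range_deg,
                by = config$rotation_step_deg)
  win <- config$translation_window_px
  best <- NULL
  for (a in angles) {
    th <- a * pi / 180
    dc0 <- be[, 1] - centroid[1]; dr0 <- be[, 2] - centroid[2]
    rc <- centroid[1] + cos(th) * dc0 - sin(th) * dr0
    rr <- centroid[2] + sin(th) * dc0 + cos(th) * dr0
    for (dr in -win[2]:win[2]) {
      for (dc in -win[1]:win[1]) {
        cs <- round(rc) + dc; rs <- round(rr) + dr
        v <- numeric(length(cs))
        for (q in seq_along(cs)) {
          v[q] <- if (cs[q] >= 1 && cs[q] <= nc && rs[q] >= 1 && rs[q] <= nr) {
            dt[rs[q], cs[q]]
          } else sentinel
        }
        mag <- sqrt(dc^2 + dr^2)
        sc <- mean(v) + config$motion_penalty * mag
        if (is.null(best) ||
            sc < best$score - 1e-12 ||
            (abs(sc - best$score) <= 1e-12 &&
             (mag < best$mag - 1e-12 ||
              (abs(mag - best$mag) <= 1e-12 && abs(a) < abs(best$angle))))) {
          best <- list(score = sc, angle = a, dc = dc, dr = dr, mag = mag)
        }
      }
    }
  }
  best
}

# run the full pipeline on one rendered scene with the classical backend
# and return per-scene truth/estimate comparison
run_scene <- function(spec, backend = c("classic", "oracle")) {
  backend <- match.arg(backend)
  sc <- render_scene(spec)
  bk <- if (backend == "classic") classic_backend(sc$frames[[1]])
        else oracle_backend(sc$truth)
  res <- suppressMessages(
    analyze_frames(sc$frames, sc$truth$ground, bk))
  list(scene = sc, result = res, truth = sc$truth)
}
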