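#' Laser detection configuration
#'
#' Tunables for locating the two projected laser dots. The dots are assumed
#' to be among the brightest points of the image, roughly circular, and
#' nearly vertically aligned. The brightness threshold is a quantile of the
#' frame's own intensity distribution rather than a fixed level, so the
#' detector adapts to site lighting (shade vs bright sun).
#'
#' @param brightness_quantile quantile of frame intensity used as the
#'   threshold (default 0.999)
#' @param min_area,max_area blob area bounds in px^2 (defaults 3, 400)
#' @param min_circularity minimum `4*pi*A / P^2` with the perimeter taken as
#'   the blob's boundary-pixel count (default 0.6)
#' @param min_peak_margin minimum excess of a blob's peak intensity over
#'   the brightness threshold (default 30 intensity units). A projected
#'   laser dot saturates far above the high-quantile threshold, whereas
#'   spurious blobs formed by sensor noise on a dot-less frame barely
#'   clear it; the margin rejects those so that scanning a clip
#'   frame-by-frame cannot lock onto a false calibration
#' @param max_column_offset maximum horizontal offset between the two dot
#'   centers, px (default 12)
#' @param expected_separation_range admissible center-to-center distance,
#'   px (default `c(30, 600)`)
#' @return a `laser_detection_config` list
#' @export
laser_detection_config <- function(brightness_quantile = 0.999,
                                   min_area = 3, max_area = 400,
                                   min_circularity = 0.6,
                                   max_column_offset = 12,
                                   expected_separation_range = c(30, 600),
                                   min_peak_margin = 30) {
  stopifnot(brightness_quantile > 0, brightness_quantile < 1,
            min_area <= max_area, min_circularity > 0, min_circularity <= 1,
            length(expected_separation_range) == 2L, min_peak_margin >= 0)
  structure(list(brightness_quantile = brightness_quantile,
                 min_area = min_area, max_area = max_area,
                 min_circularity = min_circularity,
                 max_column_offset = max_column_offset,
                 expected_separation_range = as.numeric(expected_separation_range),
                 min_peak_margin = min_peak_margin),
            class = "laser_detection_config")
}

# blob statistics for one labelled component
# returns centroid (intensity-weighted, sub-pixel), area, boundary count,
# circularity, peak intensity
blob_stats <- function(label_img, id, pixels) {
  sel <- label_img == id
  idx <- which(sel, arr.ind = TRUE)
  w <- pixels[sel]
  area <- nrow(idx)
  # boundary pixels: any 4-neighbour outside the blob (or image border)
  nr <- nrow(label_img); nc <- ncol(label_img)
  r <- idx[, 1]; c <- idx[, 2]
  inblob <- function(rr, cc) {
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    out <- logical(length(rr))
    out[ok] <- sel[cbind(rr[ok], cc[ok])]
    out
  }
  interior <- inblob(r - 1, c) & inblob(r + 1, c) & inblob(r, c - 1) & inblob(r, c + 1)
  perim <- sum(!interior)
  circ <- if (perim > 0) 4 * pi * area / perim^2 else 0
  sw <- sum(w)
  list(center = c(col = sum(c * w) / sw, row = sum(r * w) / sw),
       area = area, perimeter = perim, circularity = circ,
       peak = max(w))
}

#' Detect the two laser dots in a frame
#'
#' Thresholds the frame at a high intensity quantile, labels the
#' superlevel blobs, filters by area, circularity, vertical alignment and
#' center separation, and returns the best-scoring vertically aligned pair
#' with intensity-weighted sub-pixel centers. When several pairs pass all
#' filters, the pair with the highest summed peak intensity wins; ties go
#' to the smaller column offset.
#'
#' @param frame a [video_frame()]
#' @param config a [laser_detection_config()]
#' @param D physical inter-laser distance in mm (default 164)
#' @return a `laser_calibration` object (see [manual_laser_annotation()]),
#'   or `NULL` when no admissible dot pair is found — the caller is then
#'   expected to fall back to manual annotation. A degenerate frame
#'   (constant intensity) returns `NULL`, never an error.
#' @export
detect_laser_dots <- function(frame, config = laser_detection_config(), D = 164) {
  px <- frame$pixels
  rng <- range(px)
  if (rng[1] == rng[2]) return(NULL)          # constant frame: nothing bright
  thr <- stats::quantile(px, config$brightness_quantile, names = FALSE)
  bw <- px >= thr
  if (!any(bw) || all(bw)) return(NULL)
  lab <- EBImage::bwlabel(bw * 1)
  nblob <- max(lab)
  if (nblob < 2L) return(NULL)
  stats <- lapply(seq_len(nblob), function(i) blob_stats(lab, i, px))
  keep <- vapply(stats, function(s) {
    s$area >= config$min_area && s$area <= config$max_area &&
      s$circularity >= config$min_circularity &&
      s$peak >= thr + config$min_peak_margin
  }, logical(1))
  stats <- stats[keep]
  if (length(stats) < 2L) return(NULL)

  best <- NULL
  for (i in seq_along(stats)) {
    for (j in seq_along(stats)) {
      if (i >= j) next
      a <- stats[[i]]; b <- stats[[j]]
      dcol <- abs(a$center["col"] - b$center["col"])
      sep <- sqrt(sum((a$center - b$center)^2))
      if (dcol > config$max_column_offset) next
      if (sep < config$expected_separation_range[1] ||
          sep > config$expected_separation_range[2]) next
      score <- a$peak + b$peak
      if (is.null(best) || score > best$score + 1e-9 ||
          (abs(score - best$score) <= 1e-9 && dcol < best$dcol)) {
        best <- list(a = a, b = b, score = score, dcol = dcol, sep = sep)
      }
    }
  }
  if (is.null(best)) return(NULL)
  pts <- list(best$a$center, best$b$center)
  ord <- order(vapply(pts, `[`, numeric(1), "row"))
  upper <- pts[[ord[1]]]; lower <- pts[[ord[2]]]
  new_laser_calibration(upper, lower, D = D, source = "automatic")
}

new_laser_calibration <- function(upper, lower, D, source) {
  x <- sqrt(sum((c(upper[1], upper[2]) - c(lower[1], lower[2]))^2))
  if (x <= 0) stop("zero separation between laser dot centers")
  structure(
    list(upper_dot = as.numeric(upper[1:2]), lower_dot = as.numeric(lower[1:2]),
         x = x, D = D, k = D / x, source = source),
    class = "laser_calibration")
}

#' @export
print.laser_calibration <- function(x, ...) {
  cat(sprintf(
    "<laser_calibration [%s]  upper (%.2f, %.2f)  lower (%.2f, %.2f)\n  x = %.3f px, D = %g mm, k = %.5f mm/px>\n",
    x$source, x$upper_dot[1], x$upper_dot[2], x$lower_dot[1], x$lower_dot[2],
    x$x, x$D, x$k))
  invisible(x)
}

#' Manual laser annotation
#'
#' Fallback path when automatic dot detection fails: the operator supplies
#' the two dot centers by clicking them. The pixel separation `x` is the
#' Euclidean distance between the points and `k = D / x`.
#'
#' @param upper,lower `(column, row)` centers; `lower` must have the larger
#'   row (it sits below `upper` in the image)
#' @param D physical inter-laser distance, mm (default 164)
#' @return a `laser_calibration` with `source = "manual"`
#' @export
manual_laser_annotation <- function(upper, lower, D = 164) {
  stopifnot(length(upper) == 2L, length(lower) == 2L)
  if (all(upper == lower)) stop("zero separation: the two points coincide")
  if (lower[2] <= upper[2]) stop("lower dot must have the larger row coordinate")
  new_laser_calibration(upper, lower, D = D, source = "manual")
}

#' Pixel-to-millimetre conversion factor
#'
#' `k = D / x`: the known physical distance between the two parallel laser
#' beams divided by their apparent separation in pixels. Because the beams
#' are parallel, `k` is valid at the pedestrian's depth regardless of the
#' distance to the camera.
#'
#' @param x pixel separation between the two dot centers (> 0)
#' @param D physical inter-laser distance in mm (default 164)
#' @return conversion factor in mm per pixel
#' @export
compute_conversion_factor <- function(x, D = 164) {
  if (any(x <= 0)) stop("pixel separation x must be positive")
  if (any(D <= 0)) stop("physical distance D must be positive")
  D / x
}

#' Convert a pixel clearance to millimetres
#'
#' `MFC = d * k`. Negative pixel distances are a contract violation here:
#' clearances below the ground line must be clipped upstream where the
#' geometry is known.
#'
#' @param d clearance in pixels (>= 0)
#' @param k conversion factor mm/px (> 0)
#' @return clearance in mm
#' @export
clearance_to_mm <- function(d, k) {
  if (any(d < 0)) stop("negative pixel clearance: clip below-ground values upstream")
  if (any(k <= 0)) stop("conversion factor k must be positive")
  d * k
}

#' Serialize / deserialize a calibration to JSON
#' @param cal a `laser_calibration`
#' @param path output file; when `NULL` the JSON string is returned
#' @return the path (invisibly) or a JSON string
#' @export
calibration_to_json <- function(cal, path = NULL) {
  obj <- list(upper = cal$upper_dot, lower = cal$lower_dot,
              x_px = cal$x, D_mm = cal$D, k_mm_per_px = cal$k,
              source = cal$source)
  txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(path)
}

#' @rdname calibration_to_json
#' @param json path to a JSON file or a JSON string
#' @export
calibration_from_json <- function(json) {
  obj <- jsonlite::fromJSON(json)
  new_laser_calibration(obj$upper, obj$lower, D = obj$D_mm, source = obj$source)
}
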