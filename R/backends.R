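#' Segmentation backends
#'
#' Footwear instance segmentation is pluggable behind a one-capability
#' contract: a backend maps a [video_frame()] to an unordered, unlabeled
#' list of 0–2 candidate footwear masks. Three backends ship with the
#' package:
#'
#' * [oracle_backend()] — reads masks straight from synthetic scene truth
#'   (merging them into one when the silhouettes touch, as an instance
#'   detector confronted with overlapping feet would);
#' * [classic_backend()] — classical silhouette extraction for synthetic
#'   fixtures: background subtraction against a cached empty-walkway frame,
#'   thresholding, connected components, keep the two largest components
#'   above a minimum area. It is deterministic and dependency-light and is
#'   not claimed to work on real footage;
#' * [mask_dir_backend()] / [coco_backend()] — ingest externally produced
#'   masks (per-frame binary PNGs, or COCO-style polygon annotations), the
#'   route by which a trained neural instance detector (e.g. a Mask R-CNN
#'   run at detection confidence 0.7) plugs into the pipeline.
#'
#' @name segmentation_backends
NULL

new_backend <- function(name, fn) {
  structure(list(name = name, segment = fn), class = "segmentation_backend")
}

#' @export
print.segmentation_backend <- function(x, ...) {
  cat(sprintf("<segmentation_backend '%s'>\n", x$name))
  invisible(x)
}

#' Run a segmentation backend on one frame
#'
#' Returns 0–2 unlabeled masks with tight bounding boxes and bottom edges.
#' A backend failure is logged and treated as zero masks, never an error.
#'
#' @param frame a [video_frame()]
#' @param backend a backend from [segmentation_backends]
#' @return list of `footwear_mask` objects with `role = "unknown"`
#' @export
segment_footwear <- function(frame, backend) {
  stopifnot(inherits(backend, "segmentation_backend"))
  res <- tryCatch(backend$segment(frame),
                  error = function(e) {
                    warning(sprintf("backend '%s' failed on frame %d: %s",
                                    backend$name, frame$index, conditionMessage(e)))
                    list()
                  })
  res
}

#' Oracle backend fed from synthetic scene truth
#'
#' Returns the ground-truth masks for each frame. When the swing and
#' stance silhouettes form a single connected component (double support),
#' their union is returned as one mask — emulating a detector that cannot
#' separate overlapping feet — which is what drives the `OVERLAP` state.
#'
#' @param truth a `scene_truth` from [render_scene()]
#' @return a segmentation backend
#' @export
oracle_backend <- function(truth) {
  new_backend("oracle", function(frame) {
    fi <- frame$index
    tm <- truth$masks[[as.character(fi)]]
    if (is.null(tm) || length(tm) == 0L) return(list())
    if (length(tm) == 2L && truth$n_components[[as.character(fi)]] == 1L) {
      full <- mask_full(tm[[1]]) | mask_full(tm[[2]])
      m <- footwear_mask(full, frame_index = fi, provenance = "oracle")
      return(list(m))
    }
    lapply(tm, function(m) { m$role <- "unknown"; m$provenance <- "oracle"; m })
  })
}

#' Classical background-subtraction backend
#'
#' Subtracts a cached empty-walkway reference frame, thresholds the
#' absolute difference, labels connected components, and keeps the (at
#' most two) largest components whose area exceeds `min_area`.
#'
#' @param background a [video_frame()] of the empty scene (a `NO_ONE`
#'   frame)
#' @param min_diff minimum absolute intensity difference counted as
#'   foreground (default 40, i.e. silhouettes at least ~16% of full range
#'   darker or brighter than the background)
#' @param min_area minimum component area in px^2 (default 150)
#' @return a segmentation backend
#' @export
classic_backend <- function(background, min_diff = 40, min_area = 150) {
  bg <- background$pixels
  new_backend("classic", function(frame) {
    fg <- abs(frame$pixels - bg) >= min_diff
    if (!any(fg)) return(list())
    lab <- EBImage::bwlabel(fg * 1)
    sizes <- tabulate(lab[lab > 0], nbins = max(lab))
    ids <- which(sizes >= min_area)
    if (length(ids) == 0L) return(list())
    ids <- ids[order(sizes[ids], decreasing = TRUE)]
    ids <- ids[seq_len(min(2L, length(ids)))]
    lapply(ids, function(id) {
      footwear_mask(lab == id, frame_index = frame$index, provenance = "backend")
    })
  })
}

#' Backend reading per-frame binary PNG masks
#'
#' Expects files named `frame_{index}_mask_{i}.png` in `dir`, one file per
#' instance, non-zero pixels marking the mask.
#'
#' @param dir directory of mask PNGs
#' @return a segmentation backend
#' @export
mask_dir_backend <- function(dir) {
  files <- list.files(dir, pattern = "^frame_\\d+_mask_\\d+\\.png$")
  fidx <- as.integer(sub("^frame_(\\d+)_mask_\\d+\\.png$", "\\1", files))
  new_backend("masks", function(frame) {
    sel <- files[fidx == frame$index]
    lapply(sel, function(f) {
      m <- as_gray255(png::readPNG(file.path(dir, f))) > 127
      footwear_mask(m, frame_index = frame$index, provenance = "backend")
    })
  })
}

# scanline even-odd polygon fill; poly is a matrix with columns col,row
rasterize_polygon <- function(poly, height, width) {
  out <- matrix(FALSE, height, width)
  xs <- poly[, 1]; ys <- poly[, 2]
  n <- nrow(poly)
  for (r in seq_len(height)) {
    y <- r  # sample at integer row coordinates
    crossings <- numeric(0)
    j <- n
    for (i in seq_len(n)) {
      if ((ys[i] > y) != (ys[j] > y)) {
        xc <- xs[i] + (y - ys[i]) / (ys[j] - ys[i]) * (xs[j] - xs[i])
        crossings <- c(crossings, xc)
      }
      j <- i
    }
    if (length(crossings) >= 2L) {
      crossings <- sort(crossings)
      for (kk in seq(1L, length(crossings) - 1L, by = 2L)) {
        c0 <- ceiling(crossings[kk]); c1 <- floor(crossings[kk + 1L])
        if (c1 >= c0) out[r, max(1L, c0):min(width, c1)] <- TRUE
      }
    }
  }
  out
}

#' Backend reading COCO-style polygon annotations
#'
#' Reads a COCO-style JSON file: annotations with category name
#' `"footwear"` are rasterized (even-odd scanline fill of the polygon)
#' into per-frame masks. The `image_id` of each annotation is matched to
#' the frame index.
#'
#' @param json path to the COCO-style JSON file
#' @param height,width frame dimensions used for rasterization
#' @return a segmentation backend
#' @export
coco_backend <- function(json, height, width) {
  obj <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  cat_ids <- vapply(obj$categories, function(ct)
    if (identical(ct$name, "footwear")) ct$id else NA_integer_, numeric(1))
  cat_ids <- cat_ids[!is.na(cat_ids)]
  anns <- Filter(function(a) a$category_id %in% cat_ids, obj$annotations)
  new_backend("coco", function(frame) {
    sel <- Filter(function(a) a$image_id == frame$index, anns)
    lapply(sel, function(a) {
      seg <- unlist(a$segmentation[[1]])
      poly <- cbind(seg[seq(1, length(seg), 2)], seg[seq(2, length(seg), 2)])
      footwear_mask(rasterize_polygon(poly, height, width),
                    frame_index = frame$index, provenance = "backend")
    })
  })
}
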