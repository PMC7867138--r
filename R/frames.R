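#' Video frames and the ground plane
#'
#' A `video_frame` is one grayscale image of a sequence: a matrix of
#' intensities in \[0, 255\] indexed `[row, column]` with the origin at the
#' top-left corner (rows increase downward, columns rightward), plus a
#' non-negative frame index. All detection operates on this unit. Colour
#' images are converted to luminance on load.
#'
#' @param pixels numeric matrix of intensities in \[0, 255\], `[row, column]`
#' @param index non-negative integer frame number, unique within a sequence
#' @return an object of class `video_frame` with fields `index`, `pixels`,
#'   `height`, `width`
#' @export
video_frame <- function(pixels, index = 0L) {
  stopifnot(is.matrix(pixels), nrow(pixels) >= 1L, ncol(pixels) >= 1L)
  if (any(pixels < 0 | pixels > 255)) {
    stop("frame intensities must lie within [0, 255]")
  }
  if (index < 0) stop("frame index must be non-negative")
  structure(
    list(index = as.integer(index), pixels = pixels,
         height = nrow(pixels), width = ncol(pixels)),
    class = "video_frame")
}

#' @export
print.video_frame <- function(x, ...) {
  cat(sprintf("<video_frame #%d  %d x %d px  intensity [%g, %g]>\n",
              x$index, x$height, x$width, min(x$pixels), max(x$pixels)))
  invisible(x)
}

# luminance conversion for an array as returned by png::readPNG ([0,1])
as_gray255 <- function(arr) {
  if (is.matrix(arr)) return(arr * 255)
  if (length(dim(arr)) == 3L) {
    ch <- dim(arr)[3]
    if (ch >= 3L) {
      return((0.299 * arr[, , 1] + 0.587 * arr[, , 2] + 0.114 * arr[, , 3]) * 255)
    }
    return(arr[, , 1] * 255)
  }
  stop("unsupported image array layout")
}

#' Read a single PNG image as a video frame
#'
#' @param path path to a PNG file
#' @param index frame index to attach
#' @return a [video_frame()]
#' @export
read_frame_png <- function(path, index = 0L) {
  video_frame(as_gray255(png::readPNG(path)), index = index)
}

#' Read an image sequence from a directory
#'
#' Loads all `.png` files in `dir`, ordered by the first run of digits in
#' each file name (so `frame_00010.png` sorts after `frame_00009.png`
#' regardless of lexicographic order). Frame indices are taken from those
#' digits.
#'
#' @param dir directory containing `frame_*.png` files
#' @return list of [video_frame()] objects
#' @export
read_frame_sequence <- function(dir) {
  files <- list.files(dir, pattern = "\\.png$", full.names = TRUE)
  if (length(files) == 0L) stop("no PNG frames found in ", dir)
  num <- suppressWarnings(as.integer(sub("^\\D*(\\d+).*$", "\\1", basename(files))))
  if (anyNA(num)) num <- seq_along(files)
  ord <- order(num)
  mapply(function(f, i) read_frame_png(f, index = i),
         files[ord], num[ord], SIMPLIFY = FALSE, USE.NAMES = FALSE)
}

#' Write a frame to PNG
#'
#' Intensities are rounded to 8-bit levels so that a write/read round trip
#' is exact (bit-identical outputs for identical inputs).
#' @param frame a [video_frame()]
#' @param path output path
#' @export
write_frame_png <- function(frame, path) {
  png::writePNG(round(frame$pixels) / 255, path)
  invisible(path)
}

#' Define the ground plane from two image points
#'
#' The walkway surface appears in the sagittal view as a near-horizontal
#' line, supplied by the operator as two clicked points `(column, row)`.
#' The line may never be vertical; slopes steeper than 0.2 draw a
#' validation warning since the camera is assumed aligned with the walkway.
#'
#' @param p1,p2 numeric length-2 vectors `(column, row)`
#' @return object of class `ground_plane` with fields `p1`, `p2`, `slope`,
#'   `intercept` (row at column 0)
#' @export
ground_plane <- function(p1, p2) {
  stopifnot(length(p1) == 2L, length(p2) == 2L)
  if (p1[1] == p2[1]) stop("ground plane is vertical: p1 and p2 share a column")
  slope <- (p2[2] - p1[2]) / (p2[1] - p1[1])
  if (abs(slope) > 0.2) {
    warning(sprintf("ground plane slope %.3f exceeds 0.2; check the two points", slope))
  }
  structure(
    list(p1 = as.numeric(p1), p2 = as.numeric(p2),
         slope = slope, intercept = p1[2] - slope * p1[1]),
    class = "ground_plane")
}

#' Row of the ground line at given columns
#' @param ground a [ground_plane()]
#' @param col column coordinate(s)
#' @return interpolated row coordinate(s) of the walkway surface
#' @export
ground_row_at <- function(ground, col) {
  ground$intercept + ground$slope * col
}

#' Mirror a frame horizontally
#'
#' Utility for direction-invariance checks: reflects the pixel grid about
#' the vertical midline.
#' @param frame a [video_frame()]
#' @return the mirrored [video_frame()]
#' @export
mirror_frame <- function(frame) {
  video_frame(frame$pixels[, frame$width:1, drop = FALSE], index = frame$index)
}
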