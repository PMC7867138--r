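#' Bland-Altman plot
#'
#' Differences against means with the bias line and 95% limits of
#' agreement.
#'
#' @param ba result of [bland_altman_stats()]
#' @param ... passed to [graphics::plot()]
#' @return invisibly, `ba`
#' @export
plot_bland_altman <- function(ba, ...) {
  graphics::plot(ba$points$mean, ba$points$diff,
                 xlab = "Mean of paired measurements (mm)",
                 ylab = "Difference (mm)", pch = 19, col = "grey30", ...)
  graphics::abline(h = ba$bias, lty = 1)
  graphics::abline(h = ba$limits, lty = 2)
  invisible(ba)
}

#' Plot a stride's clearance trajectory and quintic fit
#'
#' Clearance samples (solid points, with occlusion-recovered frames
#' marked) and the fitted quintic (dotted line), plus the extracted MFC
#' point when available.
#'
#' @param stride a fitted `stride`
#' @param mfc optional `mfc_estimate` from [locate_mfc()]
#' @param ... passed to [graphics::plot()]
#' @return invisibly, `stride`
#' @export
plot_stride <- function(stride, mfc = NULL, ...) {
  pts <- stride$points
  graphics::plot(pts$frame_index, pts$clearance_px,
                 xlab = "Frame", ylab = "Clearance (px)",
                 pch = ifelse(pts$provenance == "occlusion_recovery", 1, 19), ...)
  if (!is.null(stride$coefficients)) {
    xx <- seq(min(pts$frame_index), max(pts$frame_index), length.out = 200)
    graphics::lines(xx, poly_eval(stride$coefficients, xx), lty = 3)
  }
  if (!is.null(mfc)) {
    graphics::points(mfc$frame_index, mfc$d_px, pch = 4, cex = 1.5, col = "red")
  }
  invisible(stride)
}
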