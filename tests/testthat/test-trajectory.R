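# evaluate a fitted stride's frame-basis coefficients
poly_eval_frames <- function(fit, frames) {
  sapply(frames, function(f) sum(fit$coefficients * f^(seq_along(fit$coefficients) - 1)))
}

make_mask_at <- function(col, width = 1920) {
  full <- matrix(FALSE, 100, width)
  full[40:60, max(1, col - 10):min(width, col + 10)] <- TRUE
  footwear_mask(full)
}

test_that("walking direction follows the side of first detection", {
  expect_identical(infer_walking_direction(make_mask_at(200), 1920), "left_to_right")
  expect_identical(infer_walking_direction(make_mask_at(1800), 1920), "right_to_left")
  expect_message(
    dirn <- infer_walking_direction(make_mask_at(960), 1920), "midline")
  expect_identical(dirn, "right_to_left")
})

test_that("strides are cut at sustained stationarity and short runs dropped", {
  # two strides of forward motion separated by a 5-frame stationary gap
  cols <- c(100 + 8 * (0:11),            # stride 1: frames 1..12
            rep(196, 5),                 # stationary: frames 13..17
            196 + 8 * (1:12))            # stride 2: frames 18..29
  tk <- stride_track(seq_along(cols), rep(10, length(cols)), cols)
  st <- segment_strides(tk, "left_to_right")
  expect_length(st, 2L)
  b1 <- range(st[[1]]$points$frame_index)
  b2 <- range(st[[2]]$points$frame_index)
  expect_lte(abs(b1[1] - 1), 1); expect_lte(abs(b1[2] - 12), 1)
  expect_lte(abs(b2[1] - 18), 1); expect_lte(abs(b2[2] - 29), 1)

  # monotone track: a single stride
  tk2 <- stride_track(1:20, rep(5, 20), 100 + 6 * (1:20))
  expect_length(segment_strides(tk2, "left_to_right"), 1L)

  # below the minimum supported length: dropped with a message
  tk3 <- stride_track(1:5, rep(5, 5), 100 + 6 * (1:5))
  expect_message(st3 <- segment_strides(tk3, "left_to_right"), "partial stride")
  expect_length(st3, 0L)
})

test_that("a sampled quintic is recovered to numerical precision", {
  u <- seq(-1, 1, length.out = 20)
  frames <- seq(1, 20)                       # internal map sends these to u
  y <- u^5 - 2 * u^3 + u
  tk <- stride_track(frames, y - min(y), 100 + 7 * frames)
  st <- structure(list(points = tk, direction = "left_to_right"),
                  class = "stride")
  fit <- fit_quintic_trajectory(st)
  expect_lt(max(abs(fit$coefficients_scaled -
                      c(-min(y), 1, 0, -2, 0, 1))), 1e-9)
  expect_lt(fit$fit_residual_rms, 1e-9)
  # coefficients mapped back to the frame basis evaluate identically
  expect_lt(max(abs(poly_eval_frames(fit, frames) - tk$clearance_px)), 1e-8)
})

test_that("quintic fit is unbiased under Gaussian noise", {
  u <- seq(-1, 1, length.out = 30)
  frames <- seq_len(30)
  truth <- c(3, 1, 0, -2, 0, 1)
  y0 <- truth[1] + truth[2] * u + truth[4] * u^3 + truth[6] * u^5
  coefs <- withr::with_seed(99, {
    t(replicate(50, {
      y <- y0 + rnorm(30, 0, 0.5)
      st <- structure(list(points = data.frame(
        frame_index = frames, clearance_px = y, centroid_col = frames,
        provenance = "backend")), class = "stride")
      fit_quintic_trajectory(st)$coefficients_scaled
    }))
  })
  bias <- colMeans(coefs) - truth
  se <- apply(coefs, 2, sd) / sqrt(nrow(coefs))
  expect_true(all(abs(bias) <= 3 * se + 1e-12))
})

test_that("degenerate stride supports are rejected", {
  st7 <- structure(list(points = data.frame(
    frame_index = 1:7, clearance_px = (1:7)^2, centroid_col = 1:7,
    provenance = "backend")), class = "stride")
  expect_error(fit_quintic_trajectory(st7), "at least 8 points")
  st_dup <- structure(list(points = data.frame(
    frame_index = rep(1:5, 2), clearance_px = rep(1:5, 2),
    centroid_col = rep(1:5, 2), provenance = "backend")), class = "stride")
  expect_error(fit_quintic_trajectory(st_dup), "distinct abscissae")
})

test_that("every fitted curve has at most three inflection points", {
  for (s in 1:10) {
    pts <- withr::with_seed(s, data.frame(
      frame_index = 1:25,
      clearance_px = abs(rnorm(25, 20, 8)),
      centroid_col = 1:25, provenance = "backend"))
    st <- fit_quintic_trajectory(structure(list(points = pts), class = "stride"))
    d2 <- st$coefficients_scaled
    d2 <- d2[-1] * seq_len(5); d2 <- d2[-1] * seq_len(4)  # second derivative
    uu <- seq(-1, 1, length.out = 2000)
    vals <- d2[1] + d2[2] * uu + d2[3] * uu^2 + d2[4] * uu^3
    sign_changes <- sum(diff(sign(vals[vals != 0])) != 0)
    expect_lte(sign_changes, 3L)
  }
})

test_that("the raw-series MFC is the lowest interior local minimum", {
  y <- c(30, 18, 9, 14, 25, 12, 31)
  st <- structure(list(points = data.frame(
    frame_index = seq_along(y), clearance_px = y, centroid_col = seq_along(y),
    provenance = "backend")), class = "stride")
  est <- locate_mfc(st, method = "raw_series")
  expect_equal(est$d_px, 9)
  expect_identical(est$frame_index, 3L)     # index 2 when counting from 0
})

test_that("the fitted-curve MFC picks the lower of two local minima", {
  # quintic with maxima at u = -0.8, 0.3 and minima at u = -0.2, 0.7
  roots <- c(-0.8, -0.2, 0.3, 0.7)
  dcoef <- 1
  for (r in roots) dcoef <- mfce:::poly_mul(dcoef, c(-r, 1))
  hcoef <- c(0, dcoef / seq_along(dcoef))    # antiderivative
  h <- function(u) mfce:::poly_eval(hcoef, u)
  # affinely map so the two minima sit at 12.0 and 9.5 px (the higher
  # minimum of h gets 12 so the map preserves orientation, A > 0)
  u_min <- c(-0.2, 0.7)
  hi <- u_min[which.max(h(u_min))]; lo <- u_min[which.min(h(u_min))]
  A <- (12 - 9.5) / (h(hi) - h(lo))
  B <- 12 - A * h(hi)
  u <- seq(-1, 1, length.out = 31)
  st <- structure(list(points = data.frame(
    frame_index = seq_along(u), clearance_px = A * h(u) + B,
    centroid_col = seq_along(u), provenance = "backend")), class = "stride")
  est <- locate_mfc(fit_quintic_trajectory(st))
  expect_equal(est$d_px, 9.5, tolerance = 1e-6)
  expect_lte(abs(est$frame_index - (16 + lo * 15)), 1)
})

test_that("strides without an interior minimum yield no estimate", {
  st <- structure(list(points = data.frame(
    frame_index = 1:12, clearance_px = seq(2, 35, length.out = 12),
    centroid_col = 1:12, provenance = "backend")), class = "stride")
  fit <- fit_quintic_trajectory(st)
  expect_message(est <- locate_mfc(fit), "no interior local minimum")
  expect_null(est)
})

test_that("fitted and raw MFC agree on noise-free synthetic strides", {
  traj <- make_swing_trajectory(scene_spec_small(seed = 1, h_b = 10))
  st <- structure(list(points = data.frame(
    frame_index = seq_len(nrow(traj)), clearance_px = traj$clearance_px,
    centroid_col = traj$col, provenance = "backend")), class = "stride")
  fit <- fit_quintic_trajectory(st)
  a <- locate_mfc(fit, method = "fitted_curve")
  b <- locate_mfc(fit, method = "raw_series")
  expect_lt(abs(a$d_px - b$d_px), 2)
  expect_lte(abs(a$frame_index - b$frame_index), 2L)
})

test_that("pixel estimates convert to mm through the calibration", {
  st <- structure(list(points = data.frame(
    frame_index = 1:9, clearance_px = c(9, 7, 5.2, 4.6, 4.4, 4.8, 6, 8, 10.5),
    centroid_col = 10 * (1:9), provenance = "backend")), class = "stride")
  fit <- fit_quintic_trajectory(st)
  cal <- manual_laser_annotation(c(50, 10), c(50, 10 + 164 / 1.59), D = 164)
  out <- estimate_pedestrian_mfc(list(fit), cal, "p1")
  expect_identical(nrow(out$estimates), 1L)
  expect_equal(out$estimates$mfc_mm, out$estimates$d_px * cal$k)
  expect_true(out$calibrated)

  px_only <- estimate_pedestrian_mfc(list(fit), NULL, "p1")
  expect_false(px_only$calibrated)
  expect_true(is.na(px_only$estimates$mfc_mm))
  expect_true(is.na(px_only$mfc_min_mm))
  # the arithmetic itself: d = 4.4 px at k = 1.59 gives 6.996 mm
  expect_equal(clearance_to_mm(4.4, 1.59), 6.996)
})

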