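test_that("conversion factor follows k = D / x and is monotone in x", {
  expect_identical(compute_conversion_factor(164, 164), 1)
  expect_identical(compute_conversion_factor(82, 164), 2)
  expect_identical(compute_conversion_factor(328, 164), 0.5)
  expect_error(compute_conversion_factor(0), "positive")
  expect_error(compute_conversion_factor(-3), "positive")
  ks <- compute_conversion_factor(seq(20, 800, by = 7), 164)
  expect_true(all(diff(ks) < 0))
})

test_that("pixel clearance converts to mm as d * k", {
  expect_identical(clearance_to_mm(0, 3.2), 0)
  expect_equal(clearance_to_mm(10, 1.59), 15.9)
  # at ~0.74 mm/px a 6.8 px error corresponds to about 5 mm
  expect_equal(clearance_to_mm(6.8, 0.735), 5.0, tolerance = 1e-3)
  expect_error(clearance_to_mm(-1, 1), "clip")
  expect_error(clearance_to_mm(1, 0), "positive")
})

test_that("manual annotation measures Euclidean separation", {
  cal <- manual_laser_annotation(c(100, 50), c(100, 214), D = 164)
  expect_equal(cal$x, 164)
  expect_equal(cal$k, 1.0)
  expect_identical(cal$source, "manual")

  cal2 <- manual_laser_annotation(c(100, 50), c(103, 214), D = 164)
  expect_equal(cal2$x, sqrt(3^2 + 164^2))
  expect_equal(cal2$k, 164 / sqrt(3^2 + 164^2))

  expect_error(manual_laser_annotation(c(100, 50), c(100, 50)), "separation")
  expect_error(manual_laser_annotation(c(100, 50), c(100, 40)), "larger row")
})

test_that("laser dots are detected with sub-pixel accuracy on a clean frame", {
  fr <- disc_frame(1080, 1920, list(c(900, 300), c(900, 420)), radius = 5)
  cal <- detect_laser_dots(fr)
  expect_false(is.null(cal))
  expect_lt(abs(cal$upper_dot[1] - 900), 0.5)
  expect_lt(abs(cal$upper_dot[2] - 300), 0.5)
  expect_lt(abs(cal$lower_dot[2] - 420), 0.5)
  expect_equal(cal$x, 120, tolerance = 0.5)
  expect_equal(cal$k, cal$D / cal$x)
  expect_identical(cal$source, "automatic")
})

test_that("degenerate and empty frames yield not-found, never an error", {
  black <- video_frame(matrix(0, 200, 300))
  expect_null(detect_laser_dots(black))
  flat <- video_frame(matrix(137, 200, 300))
  expect_null(detect_laser_dots(flat))
})

test_that("an elongated bright streak is rejected by circularity", {
  fr <- disc_frame(800, 1200, list(c(300, 100), c(300, 220)), radius = 5,
                   intensity = 250,
                   streak = c(500, 150, 60, 1), streak_intensity = 255)
  cfg <- laser_detection_config()
  # independent check: enumerate blobs above the threshold and apply the
  # area/circularity filters by explicit counting
  px <- fr$pixels
  thr <- quantile(px, cfg$brightness_quantile)
  lab <- EBImage::bwlabel((px >= thr) * 1)
  sizes <- tabulate(lab[lab > 0], nbins = max(lab))
  in_area <- which(sizes >= cfg$min_area & sizes <= cfg$max_area)
  circ <- vapply(in_area, function(id) {
    sel <- lab == id
    idx <- which(sel, arr.ind = TRUE)
    boundary <- 0L
    for (q in seq_len(nrow(idx))) {
      r <- idx[q, 1]; cl <- idx[q, 2]
      nb <- c(r > 1 && sel[r - 1, cl], r < nrow(sel) && sel[r + 1, cl],
              cl > 1 && sel[r, cl - 1], cl < ncol(sel) && sel[r, cl + 1])
      if (!all(nb)) boundary <- boundary + 1L
    }
    4 * pi * nrow(idx) / boundary^2
  }, numeric(1))
  expect_identical(sum(circ < cfg$min_circularity), 1L)  # only the streak fails

  cal <- detect_laser_dots(fr, cfg)
  expect_false(is.null(cal))
  expect_lt(abs(cal$upper_dot[2] - 100), 0.5)
  expect_lt(abs(cal$lower_dot[2] - 220), 0.5)
})

test_that("detection succeeds on seeded synthetic laser frames with accurate k", {
  n <- 50
  center_err <- numeric(0)
  k_rel_err <- numeric(0)
  found <- 0L
  for (s in seq_len(n)) {
    lf <- synthetic_laser_frame(seed = 1000 + s)
    cal <- detect_laser_dots(lf$frame)
    if (!is.null(cal)) {
      found <- found + 1L
      center_err <- c(center_err,
                      sqrt(sum((cal$upper_dot - lf$upper)^2)),
                      sqrt(sum((cal$lower_dot - lf$lower)^2)))
      k_rel_err <- c(k_rel_err, abs(cal$k - lf$k_true) / lf$k_true)
    }
  }
  expect_identical(found, 50L)
  expect_lte(max(center_err), 0.5)
  expect_lt(max(k_rel_err), 0.01)
})

test_that("manual and automatic calibration agree on the same frame", {
  lf <- synthetic_laser_frame(seed = 42, noise_sigma = 0)
  auto <- detect_laser_dots(lf$frame)
  man <- manual_laser_annotation(round(lf$upper), round(lf$lower))
  expect_false(is.null(auto))
  expect_lt(abs(auto$k - man$k) / man$k, 0.01)
})

test_that("calibration JSON round-trips", {
  cal <- manual_laser_annotation(c(10, 5), c(11, 130), D = 164)
  path <- tempfile(fileext = ".json")
  calibration_to_json(cal, path)
  back <- calibration_from_json(path)
  expect_equal(back$x, cal$x)
  expect_equal(back$k, cal$k)
  expect_identical(back$source, "manual")
})

test_that("a synthetic gap rendered at known mm size is recovered in mm", {
  # 24 px gap at k = 164/120 mm/px should read back as 24 * k mm
  k <- compute_conversion_factor(120, 164)
  gap_px <- 24
  expect_equal(clearance_to_mm(gap_px, k), gap_px * 164 / 120)
  # one pixel-equivalent bound on quantized measurement
  expect_lt(abs(clearance_to_mm(round(gap_px + 0.4), k) -
                  clearance_to_mm(gap_px, k)), k * 1.0001)
})
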