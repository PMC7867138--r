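# normative transition table: one row per (previous state, mask count)
state_table <- data.frame(
  previous = rep(c("NO_ONE", "BEGIN", "FULLY_VISIBLE", "OVERLAP"), each = 3),
  n_masks = rep(0:2, times = 4),
  expected = c("NO_ONE", "BEGIN", "FULLY_VISIBLE",
               "NO_ONE", "BEGIN", "FULLY_VISIBLE",
               "NO_ONE", "OVERLAP", "FULLY_VISIBLE",
               "NO_ONE", "OVERLAP", "FULLY_VISIBLE"),
  stringsAsFactors = FALSE)

test_that("the frame-state machine is total and deterministic over all 12 pairs", {
  for (i in seq_len(nrow(state_table))) {
    expect_identical(
      classify_frame_state(state_table$previous[i], state_table$n_masks[i]),
      state_table$expected[i],
      info = sprintf("%s + %d masks", state_table$previous[i], state_table$n_masks[i]))
  }
  # entering overlap from full visibility is the occlusion trigger
  expect_identical(classify_frame_state("FULLY_VISIBLE", 1), "OVERLAP")
  # a third mask (second pedestrian) is out of scope: state held
  expect_warning(out <- classify_frame_state("FULLY_VISIBLE", 3), "previous state")
  expect_identical(out, "FULLY_VISIBLE")
})

test_that("footwear_mask computes a tight bbox and a valid bottom edge", {
  for (s in 1:20) {
    full <- random_mask(s)
    m <- footwear_mask(full)
    occ <- which(full, arr.ind = TRUE)
    expect_identical(m$bbox,
                     as.integer(c(min(occ[, 2]), min(occ[, 1]),
                                  max(occ[, 2]), max(occ[, 1]))))
    # oracle equivalence of the bottom edge
    expect_identical(unname(m$bottom_edge), unname(bf_bottom_edge(full)))
    # one entry per occupied column, every point inside the mask
    expect_identical(nrow(m$bottom_edge), length(unique(occ[, 2])))
    expect_true(all(full[m$bottom_edge[, c("row", "col")]]))
  }
  expect_error(footwear_mask(matrix(FALSE, 5, 5)), "empty")
})

test_that("clearance is the minimum vertical distance to the ground line", {
  gp <- ground_plane(c(1, 500), c(1920, 500))
  full <- matrix(FALSE, 600, 1920); full[470:480, 100:160] <- TRUE
  m <- footwear_mask(full)
  lc <- lowest_point_clearance(m, gp)
  expect_equal(lc$d, 20)
  expect_equal(unname(lc$point["row"]), 480)

  # tilted walkway: interpolate the line at the achieving column
  gp2 <- ground_plane(c(0, 500), c(1920, 520))
  full2 <- matrix(FALSE, 600, 1920); full2[480:490, 930:990] <- TRUE
  m2 <- footwear_mask(full2)
  lc2 <- lowest_point_clearance(m2, gp2)
  expect_equal(lc2$d, ground_row_at(gp2, unname(lc2$point["col"])) - 490)

  # touching the line
  full3 <- matrix(FALSE, 600, 1920); full3[480:500, 100:160] <- TRUE
  expect_equal(lowest_point_clearance(footwear_mask(full3), gp)$d, 0)

  # below the line: clipped with a warning
  full4 <- matrix(FALSE, 600, 1920); full4[490:510, 100:160] <- TRUE
  expect_warning(lc4 <- lowest_point_clearance(footwear_mask(full4), gp), "clipped")
  expect_equal(lc4$d, 0)
  expect_true(lc4$below_ground)
})

test_that("swing/stance labels follow distance from the walkway", {
  gp <- ground_plane(c(1, 500), c(400, 500))
  fa <- matrix(FALSE, 600, 400); fa[450:470, 50:110] <- TRUE    # 30 px up
  fb <- matrix(FALSE, 600, 400); fb[478:498, 200:260] <- TRUE   # 2 px up
  lab <- assign_swing_stance(list(footwear_mask(fa), footwear_mask(fb)), gp)
  expect_identical(lab[[1]]$role, "swing")
  expect_identical(mask_centroid(lab[[1]])["col"] < 150, c(col = TRUE))
  expect_identical(lab[[2]]$role, "stance")
})

test_that("double-support ties fall back to centroid displacement", {
  gp <- ground_plane(c(1, 500), c(400, 500))
  fa <- matrix(FALSE, 600, 400); fa[479:499, 50:110] <- TRUE   # both 1 px up
  fb <- matrix(FALSE, 600, 400); fb[479:499, 200:260] <- TRUE
  masks <- list(footwear_mask(fa), footwear_mask(fb))
  # no history: both unknown
  lab0 <- assign_swing_stance(masks, gp)
  expect_identical(vapply(lab0, `[[`, "", "role"), c("unknown", "unknown"))
  # with history: A moved 12 px since last frame, B moved ~0.3 px
  prev <- list(swing = mask_centroid(masks[[1]]) - c(12, 0),
               stance = mask_centroid(masks[[2]]) - c(0.3, 0))
  lab1 <- assign_swing_stance(masks, gp, prev)
  expect_identical(lab1[[1]]$role, "swing")
  expect_lt(mask_centroid(lab1[[1]])["col"], 150)
})

test_that("the oracle backend reproduces truth masks exactly and merges overlaps", {
  sc <- render_scene(scene_spec_small(seed = 11))
  bk <- oracle_backend(sc$truth)
  tr <- sc$truth
  # empty lead frame: no masks
  expect_identical(segment_footwear(sc$frames[[1]], bk), list())
  sep_frames <- setdiff(tr$walk_frames, tr$overlap_frames)
  for (fi in sep_frames[c(1, 5, 10)]) {
    out <- segment_footwear(sc$frames[[fi]], bk)
    expect_identical(length(out), 2L)
    ious <- vapply(out, function(m) {
      max(mask_iou(m, tr$masks[[as.character(fi)]]$swing),
          mask_iou(m, tr$masks[[as.character(fi)]]$stance))
    }, numeric(1))
    expect_identical(unname(ious), c(1, 1))
  }
  ov <- tr$overlap_frames[1]
  expect_identical(length(segment_footwear(sc$frames[[ov]], bk)), 1L)
})

test_that("the classical backend segments dark silhouettes accurately", {
  sc <- render_scene(scene_spec_small(seed = 12, noise_sigma = 3))
  bk <- classic_backend(sc$frames[[1]])
  tr <- sc$truth
  eval_frames <- setdiff(tr$walk_frames, union(tr$overlap_frames, tr$laser_frames))
  for (fi in eval_frames[round(seq(1, length(eval_frames), length.out = 5))]) {
    out <- segment_footwear(sc$frames[[fi]], bk)
    expect_identical(length(out), 2L)
    ious <- vapply(out, function(m) {
      max(mask_iou(m, tr$masks[[as.character(fi)]]$swing),
          mask_iou(m, tr$masks[[as.character(fi)]]$stance))
    }, numeric(1))
    expect_true(all(ious >= 0.9))
  }
})

test_that("swing/stance assignment matches truth on all non-overlap frames", {
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    run <- run_scene(scene_spec_small(
      seed = 300 + s, h_b = 5 + 4 * s,
      direction = if (s %% 2 == 0) "left_to_right" else "right_to_left"),
      backend = "oracle")
    tr <- run$truth
    sep <- setdiff(tr$walk_frames, tr$overlap_frames)
    tk <- run$result$track
    for (fi in intersect(sep, tk$frame_index)) {
      total <- total + 1L
      d_true <- tr$clearance_px[fi]
      d_est <- tk$clearance_px[tk$frame_index == fi]
      if (abs(d_est - d_true) <= 1.0) hits <- hits + 1L
    }
  }
  expect_gt(total, 100L)
  expect_identical(hits, total)  # 100% of non-overlap frames
})

test_that("backend failure degrades to zero masks with a warning", {
  boom <- structure(list(name = "boom",
                         segment = function(frame) stop("backend exploded")),
                    class = "segmentation_backend")
  fr <- video_frame(matrix(0, 10, 10))
  expect_warning(out <- segment_footwear(fr, boom), "exploded")
  expect_identical(out, list())
})

test_that("external PNG masks are ingested as a backend", {
  dir <- tempfile(); dir.create(dir)
  full <- matrix(FALSE, 40, 60); full[20:30, 10:25] <- TRUE
  png::writePNG(full * 1, file.path(dir, "frame_7_mask_1.png"))
  bk <- mask_dir_backend(dir)
  fr <- video_frame(matrix(0, 40, 60), index = 7L)
  out <- segment_footwear(fr, bk)
  expect_identical(length(out), 1L)
  expect_identical(mask_full(out[[1]]), full)
  expect_identical(segment_footwear(video_frame(matrix(0, 40, 60), index = 8L), bk),
                   list())
})

test_that("COCO-style polygon annotations rasterize to masks", {
  json <- tempfile(fileext = ".json")
  writeLines(jsonlite::toJSON(list(
    categories = list(list(id = 1, name = "footwear")),
    annotations = list(list(id = 1, image_id = 3, category_id = 1,
                            segmentation = list(c(10, 5, 30, 5, 30, 15, 10, 15))))),
    auto_unbox = TRUE), json)
  bk <- coco_backend(json, height = 30, width = 50)
  out <- segment_footwear(video_frame(matrix(0, 30, 50), index = 3L), bk)
  expect_identical(length(out), 1L)
  # interior of the rectangle is filled
  expect_true(all(mask_full(out[[1]])[6:14, 11:29]))
  expect_gte(mask_iou(mask_full(out[[1]]),
                      {m <- matrix(FALSE, 30, 50); m[5:15, 10:30] <- TRUE; m}),
             0.8)
})
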