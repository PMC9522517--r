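test_that("blob_to_bbox arithmetic and clipping", {
  b <- blob_to_bbox(list(x = 10, y = 10, diameter = 4), pad = 1)
  expect_equal(unlist(b[1, 1:4]),
               c(x_min = 7, y_min = 7, x_max = 13, y_max = 13))

  # clipped at the image corner
  b2 <- blob_to_bbox(list(x = 1, y = 1, diameter = 6), pad = 1,
                     image_size = c(20, 20))
  expect_equal(b2$x_min, 0)
  expect_equal(b2$y_min, 0)

  # pad 0: side is the diameter rounded up
  area <- 29
  d <- 2 * sqrt(area / pi)
  b3 <- blob_to_bbox(list(x = 15, y = 15, diameter = d), pad = 0)
  expect_equal(b3$x_max - b3$x_min, ceiling(d))

  expect_error(blob_to_bbox(list(x = 1, y = 1, diameter = 0)), "positive")
})

test_that("Labelme export/import round-trips boxes losslessly", {
  boxes <- data.frame(x_min = c(5, 20), y_min = c(6, 21),
                      x_max = c(9, 26), y_max = c(10, 27),
                      label = c("prickle", "prickle"),
                      region = c("tip", NA), stringsAsFactors = FALSE)
  json <- export_labelme(boxes, "img.png", c(64, 64))
  back <- import_labelme(json)
  expect_equal(back$x_min, boxes$x_min)
  expect_equal(back$y_max, boxes$y_max)
  expect_equal(back$region, boxes$region)
  # export -> import -> export is byte-stable
  expect_identical(export_labelme(back, "img.png", c(64, 64)), json)

  # empty set still produces a valid document
  empty <- import_labelme(export_labelme(boxes[0, ], "img.png", c(8, 8)))
  expect_equal(nrow(empty), 0L)

  # corners in any order are normalized
  doc <- jsonlite::fromJSON(json, simplifyVector = FALSE)
  doc$shapes[[1]]$points <- rev(doc$shapes[[1]]$points)
  flipped <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null")
  expect_equal(import_labelme(flipped)$x_min[1], 5)

  # polygons are skipped with a warning
  doc$shapes[[1]]$shape_type <- "polygon"
  poly <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null")
  expect_warning(out <- import_labelme(poly), "skipped")
  expect_equal(nrow(out), 1L)

  expect_error(export_labelme(boxes, "x.png", c(8, 8)), "exceed")
  expect_error(import_labelme('{"foo": 1}'), "shapes")
})

test_that("annotation is deterministic and boxes stay on the tongue", {
  sc <- generate_scene(scene_preset("fast", seed = 901))
  cfg <- generator_matched_config()
  b1 <- annotate_image(sc$image, sc$degraded_mask, cfg)
  b2 <- annotate_image(sc$image, sc$degraded_mask, cfg)
  expect_identical(b1, b2)
  expect_gt(nrow(b1), 0L)
  H <- dim(sc$image)[1]; W <- dim(sc$image)[2]
  expect_true(all(b1$x_min >= 0 & b1$y_min >= 0 &
                  b1$x_max <= W & b1$y_max <= H))
  refined <- refine_mask(sc$degraded_mask)
  for (i in seq_len(nrow(b1))) {
    patch <- refined[(b1$y_min[i] + 1):b1$y_max[i],
                     (b1$x_min[i] + 1):b1$x_max[i]]
    expect_true(any(patch))
  }
  # identical JSON end to end
  j1 <- export_labelme(b1, "s.png", c(H, W))
  j2 <- export_labelme(b2, "s.png", c(H, W))
  expect_identical(j1, j2)
})

test_that("a scene without prickles yields no annotations", {
  sc <- generate_scene(scene_preset("fast", seed = 902,
                                    prickles = list(n = 0L),
                                    cracks = list(n = 0L),
                                    petechiae = list(n = 0L)))
  boxes <- annotate_image(sc$image, sc$degraded_mask,
                          generator_matched_config())
  expect_equal(nrow(boxes), 0L)
})

test_that("grid search on one free parameter matches the exhaustive scan", {
  # planted 3-pixel bars: initial min_area 4 misses them
  set.seed(15)
  g <- matrix(200L, 64, 64)
  centers <- cbind(seq(8, 56, by = 10), seq(10, 58, by = 10))
  gt <- NULL
  for (i in seq_len(nrow(centers))) {
    r0 <- centers[i, 1]; c0 <- centers[i, 2]
    g[r0, c0:(c0 + 2)] <- 40L
    gt <- rbind(gt, data.frame(x_min = c0 - 3, y_min = r0 - 3,
                               x_max = c0 + 4, y_max = r0 + 2,
                               label = "prickle", region = NA_character_))
  }
  scene <- list(gray = g, mask = matrix(TRUE, 64, 64), boxes = gt)
  initial <- blob_params(min_threshold = 60, max_threshold = 100,
                         threshold_step = 10, min_repeatability = 2,
                         min_area = 4, max_area = 40,
                         min_circularity = 0.2, min_convexity = 0.4,
                         min_inertia_ratio = 0.0)
  gs <- grid_search_spec(initial, params_to_search = "min_area",
                         iou_threshold = 0.3)
  tuned <- grid_search_params(list(scene), "root_center", gs,
                              partition_fractions(0.9, 0.05, 0.05))
  # exhaustive 11-point scan of the same grid
  grid <- unique(pmax(1, round(seq(0.5, 1.5, 0.1) * 4)))
  eval_f1 <- function(ma) {
    p <- initial; p$min_area <- ma
    blobs <- detect_blobs(g, p)
    pred <- if (nrow(blobs) == 0) gt[0, 1:4] else
      do.call(rbind, lapply(seq_len(nrow(blobs)), function(i)
        blob_to_bbox(blobs[i, ], pad = 1, image_size = c(64, 64))))
    m <- match_detections(gt, pred, 0.3)
    if (2 * m$tp + m$fp + m$fn == 0) 0 else 2 * m$tp / (2 * m$tp + m$fp + m$fn)
  }
  scores <- vapply(grid, eval_f1, numeric(1))
  best <- max(scores)
  ties <- grid[scores == best]
  expected <- ties[order(abs(ties - 4), ties)][1]
  expect_equal(tuned$min_area, expected)
  expect_equal(attr(tuned, "objective"), best)
  expect_gte(attr(tuned, "objective"), attr(tuned, "initial_objective"))
  expect_gt(best, eval_f1(4))  # the search actually improved detection
})

test_that("grid search never returns an objective below the initial", {
  for (s in 1:2) {
    sc <- generate_scene(scene_preset("fast", seed = 910 + s,
                                      cracks = list(n = 0L),
                                      petechiae = list(n = 0L)))
    scene <- list(gray = to_grayscale(sc$image), mask = sc$clean_mask,
                  boxes = sc$prickle_boxes)
    init <- generator_matched_config()$detector$tip
    gs <- grid_search_spec(init, params_to_search = c("min_area",
                                                      "min_repeatability"),
                           max_cycles = 2L)
    tuned <- grid_search_params(list(scene), "tip", gs)
    expect_gte(attr(tuned, "objective"), attr(tuned, "initial_objective"))
  }
  expect_error(grid_search_params(list(), "tip",
                                  grid_search_spec(blob_params())),
               "at least one scene")
})
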