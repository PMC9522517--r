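test_that("grayscale conversion is Rec. 601 luma, rounded half-up", {
  img <- array(0, c(1, 3, 3))
  img[1, 1, ] <- c(255, 255, 255)
  img[1, 2, ] <- c(0, 0, 0)
  img[1, 3, ] <- c(255, 0, 0)
  g <- to_grayscale(img)
  expect_identical(as.vector(g), c(255L, 0L, 76L))
  expect_error(to_grayscale(matrix(0, 3, 3)), "H x W x 3")
})

test_that("shape scores match closed forms on canonical shapes", {
  s1 <- shape_scores(matrix(c(5, 5), 1, 2))
  expect_equal(s1$area, 1L)
  expect_equal(s1$perimeter, 4)
  expect_equal(s1$inertia_ratio, 1)

  # filled 10x10 square: perimeter 4s, circularity pi/4 exactly
  sq <- as.matrix(expand.grid(y = 0:9, x = 0:9))
  s2 <- shape_scores(sq)
  expect_equal(s2$perimeter, 40)
  expect_equal(s2$circularity, pi / 4)
  expect_equal(s2$convexity, 1)
  expect_equal(s2$inertia_ratio, 1)

  # 1x2 domino: crack perimeter 6
  s3 <- shape_scores(rbind(c(0, 0), c(0, 1)))
  expect_equal(s3$perimeter, 6)

  # digitized disk radius 6: frozen values from the brute-force tracer
  s4 <- shape_scores(disk_coords(6, 10, 10))
  expect_equal(s4$area, 113L)
  expect_equal(s4$perimeter, 42.627417, tolerance = 1e-6)
  expect_equal(s4$circularity, 0.781466, tolerance = 1e-4)
  expect_equal(s4$convexity, 0.875969, tolerance = 1e-4)
  expect_equal(s4$inertia_ratio, 1)

  expect_error(shape_scores(matrix(numeric(0), 0, 2)), "non-empty")
})

test_that("shape scores accept logical-matrix input", {
  m <- matrix(FALSE, 8, 8)
  m[3:5, 3:5] <- TRUE
  s <- shape_scores(m)
  expect_equal(s$area, 9L)
  expect_equal(s$perimeter, 12)  # 4s for an s x s square
})

test_that("detector finds nothing in a uniform image", {
  g <- matrix(128L, 40, 40)
  expect_equal(nrow(detect_blobs(g, blob_params())), 0L)
})

test_that("detector recovers a single dark disk with tip parameters", {
  tip <- default_config()$detector$tip
  g <- matrix(200L, 48, 48)
  g <- paint_disk(g, 25, 23, 3, 40L)   # 29 px, inside tip's [2, 40]
  blobs <- detect_blobs(g, tip)
  expect_equal(nrow(blobs), 1L)
  expect_lt(abs(blobs$x - 22), 0.5)
  expect_lt(abs(blobs$y - 24), 0.5)
  expect_equal(blobs$area, 29)
  expect_equal(blobs$repeatability, 20L)  # thresholds 60..98
})

test_that("circularity bound separates a disk from a square", {
  params <- blob_params(min_threshold = 60, max_threshold = 100,
                        threshold_step = 2, min_repeatability = 4,
                        min_area = 2, max_area = 200,
                        min_circularity = 0.8,  # root/center bound
                        min_convexity = 0.4, min_inertia_ratio = 0.4)
  g <- matrix(200L, 60, 120)
  g <- paint_disk(g, 30, 30, 6.75, 40L)  # circularity ~0.90
  g <- paint_square(g, 27, 80, 6L, 40L)  # circularity pi/4 < 0.8
  blobs <- detect_blobs(g, params)
  expect_equal(nrow(blobs), 1L)
  expect_lt(abs(blobs$x - 29), 1)
  # sanity: with the loose bound both are found
  params$min_circularity <- 0.4
  expect_equal(nrow(detect_blobs(g, params)), 2L)
})

test_that("detector equals the independent oracle on random images", {
  params <- blob_params(min_threshold = 60, max_threshold = 100,
                        threshold_step = 8, min_repeatability = 2,
                        min_area = 4, max_area = 30,
                        min_circularity = 0.3, min_convexity = 0.3,
                        min_inertia_ratio = 0.1, min_dist_between_blobs = 6)
  set.seed(99)
  for (i in 1:10) {
    g <- matrix(sample(0:255, 64 * 64, replace = TRUE), 64, 64)
    got <- detect_blobs(g, params)
    ref <- oracle_detect_blobs(g, params)
    if (is.null(ref)) {
      expect_equal(nrow(got), 0L)
    } else {
      expect_equal(nrow(got), nrow(ref))
      expect_equal(got$x, ref$x, tolerance = 1e-8)
      expect_equal(got$y, ref$y, tolerance = 1e-8)
      expect_equal(got$area, ref$area)
      expect_equal(got$repeatability, ref$repeatability)
    }
  }
})

test_that("detector responds monotonically to its parameters", {
  set.seed(5)
  g <- matrix(200L, 64, 64)
  for (i in 1:6)
    g <- paint_disk(g, sample(8:56, 1), sample(8:56, 1),
                    runif(1, 2, 4), 40L)
  base <- blob_params(min_repeatability = 4, min_area = 2, max_area = 60,
                      min_circularity = 0.3, min_convexity = 0.3,
                      min_inertia_ratio = 0.1)
  n0 <- nrow(detect_blobs(g, base))
  # raising min_repeatability never adds blobs
  stricter <- base; stricter$min_repeatability <- 12
  expect_lte(nrow(detect_blobs(g, stricter)), n0)
  # widening the area band never removes blobs
  wider <- base; wider$min_area <- 1; wider$max_area <- 200
  expect_gte(nrow(detect_blobs(g, wider)), n0)
})

test_that("blob centers shift with image translation", {
  g <- matrix(200L, 64, 64)
  g <- paint_disk(g, 20, 20, 3, 40L)
  params <- default_config()$detector$tip
  b1 <- detect_blobs(g, params)
  g2 <- matrix(200L, 64, 64)
  g2 <- paint_disk(g2, 20 + 7, 20 + 11, 3, 40L)
  b2 <- detect_blobs(g2, params)
  expect_equal(b2$x - b1$x, 11)
  expect_equal(b2$y - b1$y, 7)
})

test_that("per-region detection assigns regions and applies local filters", {
  cfg <- default_config()
  m <- matrix(TRUE, 90, 40)
  rm_ <- partition_tongue(m)  # rows 0..21 root, 22..71 middle, 72..89 tip

  # spot in the tip area only
  g <- matrix(200L, 90, 40)
  g <- paint_disk(g, 80, 20, 3, 40L)
  blobs <- detect_blobs_by_region(g, rm_, cfg$detector)
  expect_equal(nrow(blobs), 1L)
  expect_equal(blobs$region, "tip")

  # elongated crack fragment in the center: aspect ~1.45 passes the loose
  # margin filters but fails the tight root/center bounds
  g2 <- matrix(200L, 90, 40)
  g2 <- paint_ellipse(g2, 45, 20, 3.3, 2.3, 40L)
  frag <- detect_blobs(g2, cfg$detector$margin)
  expect_equal(nrow(frag), 1L)   # detectable under margin parameters
  expect_equal(nrow(detect_blobs(g2, cfg$detector$root_center)), 0L)
  expect_equal(nrow(detect_blobs_by_region(g2, rm_, cfg$detector)), 0L)

  # same appearance at the margin survives
  g3 <- matrix(200L, 90, 40)
  g3 <- paint_ellipse(g3, 45, 3, 3.3, 2.3, 40L)
  blobs3 <- detect_blobs_by_region(g3, rm_, cfg$detector)
  expect_equal(nrow(blobs3), 1L)
  expect_equal(blobs3$region, "margin")

  # missing parameters for a present region is an error
  expect_error(detect_blobs_by_region(g, rm_, cfg$detector["tip"]),
               "missing detector parameters")
})

test_that("parameter validation catches inconsistent settings", {
  expect_error(blob_params(min_threshold = 100, max_threshold = 60), "<")
  expect_error(blob_params(threshold_step = 0), "positive")
  expect_error(blob_params(min_area = 50, max_area = 10), "<=")
  expect_error(blob_params(min_circularity = 1.2), "\\[0, 1\\]")
})
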