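test_that("segmentation confusion and metrics match hand counts", {
  gt <- matrix(FALSE, 4, 4); gt[1:2, 1:2] <- TRUE
  pred <- matrix(FALSE, 4, 4); pred[1:2, 2:3] <- TRUE
  cc <- seg_confusion(gt, pred)
  expect_equal(cc, list(tp = 2L, fp = 2L, tn = 10L, fn = 2L))
  expect_equal(Reduce(`+`, cc), 16L)
  m <- seg_metrics(cc)
  expect_equal(m$iou, 1 / 3)
  expect_equal(m$precision, 0.5)
  expect_equal(m$accuracy, 0.75)

  # identity and inversion
  expect_equal(seg_confusion(gt, gt)$fp + seg_confusion(gt, gt)$fn, 0L)
  inv <- seg_confusion(gt, !gt)
  expect_equal(inv$tp + inv$tn, 0L)
  perfect <- seg_metrics(seg_confusion(gt, gt))
  expect_equal(unlist(perfect), c(iou = 1, precision = 1, accuracy = 1))

  # undefined metrics are NA, not 0
  und <- seg_metrics(list(tp = 0L, fp = 0L, tn = 5L, fn = 0L))
  expect_true(is.na(und$iou) && is.na(und$precision))
  expect_equal(seg_metrics(list(tp = 0L, fp = 1L, tn = 0L, fn = 1L))$iou, 0)

  expect_error(seg_confusion(gt, matrix(TRUE, 3, 3)), "differ")
})

test_that("bbox IoU matches arithmetic on half-open boxes", {
  a <- data.frame(x_min = 0, y_min = 0, x_max = 2, y_max = 2)
  b <- data.frame(x_min = 1, y_min = 0, x_max = 3, y_max = 2)
  c_ <- data.frame(x_min = 5, y_min = 5, x_max = 7, y_max = 7)
  expect_equal(bbox_iou(a, a), 1)
  expect_equal(bbox_iou(a, c_), 0)
  expect_equal(bbox_iou(a, b), 1 / 3)
  expect_equal(bbox_iou(b, a), 1 / 3)
})

test_that("greedy matching satisfies its count identities and edge cases", {
  boxes <- function(df) cbind(df, label = "prickle", region = NA_character_)
  gt <- data.frame(x_min = c(0, 10), y_min = c(0, 0),
                   x_max = c(4, 14), y_max = c(4, 4))
  m <- match_detections(gt, gt, 0.5)
  expect_equal(c(m$tp, m$fp, m$fn), c(2L, 0L, 0L))

  m2 <- match_detections(gt, gt[0, ], 0.5)
  expect_equal(c(m2$tp, m2$fp, m2$fn), c(0L, 0L, 2L))

  # two adjacent gt boxes, one prediction overlapping both
  gt3 <- data.frame(x_min = c(0, 4), y_min = c(0, 0),
                    x_max = c(4, 8), y_max = c(4, 4))
  pred3 <- data.frame(x_min = 1, y_min = 0, x_max = 6, y_max = 4)
  m3 <- match_detections(gt3, pred3, 0.3)
  expect_equal(c(m3$tp, m3$fn, m3$fp), c(1L, 1L, 0L))

  expect_error(match_detections(gt, gt, 0), "\\(0, 1\\]")
})

test_that("greedy matching equals optimal matching on sparse random sets", {
  set.seed(77)
  for (i in 1:20) {
    gt <- random_boxes(sample(2:6, 1))
    pred <- random_boxes(sample(2:6, 1))
    for (thr in c(0.3, 0.5)) {
      m <- match_detections(gt, pred, thr)
      expect_equal(m$tp + m$fn, nrow(gt))
      expect_equal(m$tp + m$fp, nrow(pred))
      expect_equal(m$tp, max_matching_tp(gt, pred, thr))
    }
  }
})

test_that("raising the IoU threshold never increases tp", {
  set.seed(8)
  gt <- random_boxes(5)
  pred <- random_boxes(5)
  tps <- vapply(c(0.1, 0.3, 0.5, 0.7, 0.9),
                function(t) match_detections(gt, pred, t)$tp, integer(1))
  expect_true(all(diff(tps) <= 0))
})

test_that("detection report tabulates per-region recall like Table layout", {
  m <- matrix(TRUE, 100, 40)
  rm_ <- partition_tongue(m)
  mkbox <- function(y, x) data.frame(x_min = x - 2, y_min = y - 2,
                                     x_max = x + 2, y_max = y + 2,
                                     label = "prickle",
                                     region = NA_character_)
  gt <- rbind(mkbox(10, 20),   # root
              mkbox(50, 20),   # center
              mkbox(90, 20),   # tip
              mkbox(50, 2))    # margin
  # stub detector that finds exactly the margin plant
  pred <- mkbox(50, 2)
  rep_ <- detection_report(gt, pred, rm_, 0.5)
  df <- as.data.frame(rep_)
  expect_equal(df$recall_pct[df$region == "margin"], 100)
  expect_equal(df$recall_pct[df$region == "root_center"], 0)
  expect_equal(df$recall_pct[df$region == "tip"], 0)
  expect_equal(df$recall_pct[df$region == "total"], 25)
  expect_equal(df$n_gt[df$region == "total"], sum(df$n_gt[df$region != "total"]))

  # all matched everywhere
  rep2 <- as.data.frame(detection_report(gt, gt, rm_, 0.5))
  expect_true(all(rep2$recall_pct == 100))

  # gt only in tip, none matched: other regions undefined
  rep3 <- as.data.frame(detection_report(mkbox(90, 20), mkbox(10, 20),
                                         rm_, 0.5))
  expect_equal(rep3$recall_pct[rep3$region == "tip"], 0)
  expect_true(is.na(rep3$recall_pct[rep3$region == "margin"]))

  # gt centered on background draws a warning and counts in total only
  off <- mkbox(50, 20); off$x_min <- -10; off$x_max <- -2
  expect_warning(detection_report(rbind(gt, off), gt, rm_, 0.5),
                 "background")

  # CSV rendering round-trips the table
  path <- withr::local_tempfile(fileext = ".csv")
  write_detection_report(rep_, path)
  back <- utils::read.csv(path)
  expect_equal(back$tp, df$tp)
})
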