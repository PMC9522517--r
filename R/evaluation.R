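#' Pixel-wise segmentation confusion counts
#'
#' Treats segmentation as pixel-wise classification and counts true/false
#' positives/negatives between a ground-truth and a predicted mask.
#'
#' @param gt,pred logical matrices of the same dimensions.
#' @return named list `tp`, `fp`, `tn`, `fn`; the counts sum to the pixel
#'   total.
#' @export
seg_confusion <- function(gt, pred) {
  assert_mask(gt, "gt"); assert_mask(pred, "pred")
  if (!all(dim(gt) == dim(pred))) stop("mask dimensions differ")
  list(tp = sum(gt & pred), fp = sum(!gt & pred),
       tn = sum(!gt & !pred), fn = sum(gt & !pred))
}

#' Segmentation metrics from confusion counts
#'
#' `iou = tp / (fp + fn + tp)`, `precision = tp / (tp + fp)`,
#' `accuracy = (tp + tn) / (tp + tn + fp + fn)`. A metric whose
#' denominator is zero is undefined and reported as `NA`, never as 0.
#'
#' @param c named list or vector with `tp`, `fp`, `tn`, `fn`.
#' @return named list `iou`, `precision`, `accuracy`.
#' @export
seg_metrics <- function(c) {
  ratio <- function(num, den) if (den == 0) NA_real_ else num / den
  list(iou = ratio(c$tp, c$fp + c$fn + c$tp),
       precision = ratio(c$tp, c$tp + c$fp),
       accuracy = ratio(c$tp + c$tn, c$tp + c$tn + c$fp + c$fn))
}

#' Bounding-box intersection over union
#'
#' Boxes are 0-based and half-open (`x_max`, `y_max` exclusive), as
#' produced by [blob_to_bbox()].
#'
#' @param a,b one-row data.frames (or lists) with `x_min`, `y_min`,
#'   `x_max`, `y_max`.
#' @return IoU in \[0,1\].
#' @export
bbox_iou <- function(a, b) {
  iw <- min(a$x_max, b$x_max) - max(a$x_min, b$x_min)
  ih <- min(a$y_max, b$y_max) - max(a$y_min, b$y_min)
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  area_a <- (a$x_max - a$x_min) * (a$y_max - a$y_min)
  area_b <- (b$x_max - b$x_min) * (b$y_max - b$y_min)
  inter / (area_a + area_b - inter)
}

# All-pairs IoU matrix between two box data.frames (rows gt, cols pred).
bbox_iou_matrix <- function(gt, pred) {
  iw <- outer(gt$x_max, pred$x_max, pmin) - outer(gt$x_min, pred$x_min, pmax)
  ih <- outer(gt$y_max, pred$y_max, pmin) - outer(gt$y_min, pred$y_min, pmax)
  inter <- pmax(iw, 0) * pmax(ih, 0)
  ag <- (gt$x_max - gt$x_min) * (gt$y_max - gt$y_min)
  ap <- (pred$x_max - pred$x_min) * (pred$y_max - pred$y_min)
  un <- outer(ag, ap, `+`) - inter
  out <- inter / un
  out[un <= 0] <- 0
  out
}

#' Match predicted to ground-truth boxes at an IoU threshold
#'
#' One-to-one greedy matching: candidate pairs with IoU at or above the
#' threshold are taken in order of descending IoU (ties broken by smaller
#' ground-truth index, then smaller prediction index); each box matches at
#' most once. A ground-truth box is a true positive when matched and a
#' false negative otherwise; unmatched predictions are false positives.
#' `tn` is identically 0 (undefined for detection).
#'
#' @param gt,pred box data.frames (possibly zero rows).
#' @param iou_threshold matching threshold in (0, 1\].
#' @return named list `tp`, `fp`, `tn`, `fn`, plus `gt_match` and
#'   `pred_match` (integer index vectors, `NA` = unmatched).
#' @export
match_detections <- function(gt, pred, iou_threshold = 0.5) {
  if (iou_threshold <= 0 || iou_threshold > 1)
    stop("`iou_threshold` must lie in (0, 1]")
  ng <- nrow(gt); np <- nrow(pred)
  gt_match <- rep(NA_integer_, ng); pred_match <- rep(NA_integer_, np)
  if (ng > 0L && np > 0L) {
    iou <- bbox_iou_matrix(gt, pred)
    cand <- which(iou >= iou_threshold, arr.ind = TRUE)
    if (nrow(cand) > 0L) {
      v <- iou[cand]
      ord <- order(-v, cand[, 1L], cand[, 2L])
      for (k in ord) {
        gi <- cand[k, 1L]; pi <- cand[k, 2L]
        if (is.na(gt_match[gi]) && is.na(pred_match[pi])) {
          gt_match[gi] <- pi; pred_match[pi] <- gi
        }
      }
    }
  }
  tp <- sum(!is.na(gt_match))
  list(tp = tp, fp = np - tp, tn = 0L, fn = ng - tp,
       gt_match = gt_match, pred_match = pred_match)
}

# Region group of each box center on a region map; "background" when the
# center falls on no region (or outside the map).
box_center_group <- function(boxes, region_map) {
  if (nrow(boxes) == 0L) return(character(0))
  cx <- (boxes$x_min + boxes$x_max) / 2
  cy <- (boxes$y_min + boxes$y_max) / 2
  r <- round_half_up(cy) + 1L; c_ <- round_half_up(cx) + 1L
  inside <- r >= 1L & r <= nrow(region_map) & c_ >= 1L & c_ <= ncol(region_map)
  code <- rep(0L, nrow(boxes))
  code[inside] <- region_map[cbind(r[inside], c_[inside])]
  ifelse(code == 0L, "background", region_group(code))
}

#' Per-region detection report
#'
#' Matches predictions to ground truth once, globally, then tabulates
#' recall (`tp / (tp + fn)`) and precision (`tp / (tp + fp)`) per region
#' group (root & center, tip, margin) and in total. Boxes are assigned to
#' regions by their center; a ground-truth box centered on background is
#' counted in the total row only (with a warning). Undefined cells (zero
#' denominator) are reported as `NA`.
#'
#' @param gt,pred box data.frames.
#' @param region_map integer `region_map` (see [partition_tongue()]).
#' @param iou_threshold matching threshold; 0.5 by default.
#' @return a `detection_report`: data.frame with one row per region group
#'   plus a total row; columns `region`, `n_gt`, `n_pred`, `tp`, `fn`,
#'   `fp`, `recall_pct`, `precision_pct`.
#' @export
detection_report <- function(gt, pred, region_map, iou_threshold = 0.5) {
  m <- match_detections(gt, pred, iou_threshold)
  g_gt <- box_center_group(gt, region_map)
  g_pred <- box_center_group(pred, region_map)
  if (any(g_gt == "background"))
    warning(sum(g_gt == "background"),
            " ground-truth box(es) centered on background; counted in total only")
  groups <- c("root_center", "tip", "margin")
  rows <- lapply(groups, function(g) {
    gi <- which(g_gt == g); pi <- which(g_pred == g)
    tp <- sum(!is.na(m$gt_match[gi]))
    tp_p <- sum(!is.na(m$pred_match[pi]))
    data.frame(region = g, n_gt = length(gi), n_pred = length(pi),
               tp = tp, fn = length(gi) - tp, fp = length(pi) - tp_p,
               recall_pct = if (length(gi) == 0L) NA_real_ else 100 * tp / length(gi),
               precision_pct = if (length(pi) == 0L) NA_real_ else 100 * tp_p / length(pi),
               stringsAsFactors = FALSE)
  })
  total <- data.frame(region = "total", n_gt = nrow(gt), n_pred = nrow(pred),
                      tp = m$tp, fn = m$fn, fp = m$fp,
                      recall_pct = if (nrow(gt) == 0L) NA_real_ else 100 * m$tp / nrow(gt),
                      precision_pct = if (nrow(pred) == 0L) NA_real_ else 100 * m$tp / nrow(pred),
                      stringsAsFactors = FALSE)
  structure(do.call(rbind, c(rows, list(total))),
            class = c("detection_report", "data.frame"),
            iou_threshold = iou_threshold)
}

#' @export
print.detection_report <- function(x, ...) {
  cat(sprintf("Detection report (IoU threshold %.2f)\n",
              attr(x, "iou_threshold")))
  df <- as.data.frame(x)
  df$recall_pct <- ifelse(is.na(df$recall_pct), "-",
                          sprintf("%.2f", df$recall_pct))
  df$precision_pct <- ifelse(is.na(df$precision_pct), "-",
                             sprintf("%.2f", df$precision_pct))
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a detection report as CSV
#'
#' @param report a [detection_report()] object.
#' @param path output file.
#' @export
write_detection_report <- function(report, path) {
  write.csv(as.data.frame(report), path, row.names = FALSE, na = "")
  invisible(path)
}
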