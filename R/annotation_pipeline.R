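#' Bounding box from a blob
#'
#' Axis-aligned square of side `ceiling(diameter + 2 pad)` centered on the
#' blob center, clipped to the image. Boxes are 0-based and half-open
#' (`x_max`, `y_max` exclusive).
#'
#' @param blob one-row blob data.frame (or list) with `x`, `y`,
#'   `diameter` and optionally `region`.
#' @param pad padding in pixels on each side (default 1).
#' @param image_size `(H, W)`; when given, the box is clipped to it.
#' @return one-row box data.frame: `x_min`, `y_min`, `x_max`, `y_max`,
#'   `label`, `region`.
#' @export
blob_to_bbox <- function(blob, pad = 1, image_size = NULL) {
  if (blob$diameter <= 0) stop("blob diameter must be positive")
  side <- ceiling(blob$diameter + 2 * pad)
  x_min <- floor(blob$x - side / 2 + 0.5)
  y_min <- floor(blob$y - side / 2 + 0.5)
  x_max <- x_min + side
  y_max <- y_min + side
  if (!is.null(image_size)) {
    x_min <- max(0, x_min); y_min <- max(0, y_min)
    x_max <- min(image_size[2], x_max); y_max <- min(image_size[1], y_max)
  }
  data.frame(x_min = x_min, y_min = y_min, x_max = x_max, y_max = y_max,
             label = "prickle",
             region = if (!is.null(blob$region)) blob$region else NA_character_,
             stringsAsFactors = FALSE)
}

#' Annotate prickles on a tongue image
#'
#' The full classic-CV annotation chain: refine the mask, partition the
#' tongue, detect blobs per region, filter by chromatic aberration, and
#' convert the surviving blobs to padded bounding boxes sorted by
#' `(y_min, x_min)`. Deterministic: identical inputs and config give
#' identical boxes.
#'
#' With `partition = FALSE` the partition is still computed (for region
#' bookkeeping) but a single parameter set -- the margin entry, the loose
#' one -- and its color bound are applied everywhere, which is the
#' baseline the partitioned run is compared against.
#'
#' @param image `H x W x 3` array, 8-bit values.
#' @param mask logical tongue mask of the same height/width (refined or
#'   not; it is refined internally).
#' @param config configuration list (see [default_config()]).
#' @param partition logical; apply per-region parameters (default) or the
#'   single margin set everywhere.
#' @return box data.frame (possibly zero rows) with `x_min`, `y_min`,
#'   `x_max`, `y_max`, `label`, `region`.
#' @export
annotate_image <- function(image, mask, config = default_config(),
                           partition = TRUE) {
  d <- dim(image)
  if (length(d) != 3L || !all(d[1:2] == dim(mask)))
    stop("image and mask sizes differ")
  gray <- to_grayscale(image)
  refined <- refine_mask(mask)
  fr <- partition_fractions(config$partition$f_root, config$partition$f_tip,
                            config$partition$f_margin)
  region_map <- partition_tongue(refined, fr,
                                 orientation = config$partition$orientation)
  if (partition) {
    blobs <- detect_blobs_by_region(gray, region_map, config$detector)
    blobs <- filter_blobs_by_color(blobs, image, config$reference_colors,
                                   config$detector)
  } else {
    blobs <- detect_blobs(gray, config$detector$margin)
    if (nrow(blobs) > 0L) {
      r <- round_half_up(blobs$y) + 1L; c_ <- round_half_up(blobs$x) + 1L
      inside <- r >= 1L & r <= nrow(refined) & c_ >= 1L & c_ <= ncol(refined)
      on_tongue <- inside
      on_tongue[inside] <- refined[cbind(r[inside], c_[inside])]
      blobs <- blobs[on_tongue, , drop = FALSE]
    }
    if (nrow(blobs) > 0L) {
      code <- region_map[cbind(round_half_up(blobs$y) + 1L,
                               round_half_up(blobs$x) + 1L)]
      blobs$region <- region_name(pmax(code, 1L))  # bookkeeping only
      all_margin <- blobs
      all_margin$region <- "margin"
      kept <- filter_blobs_by_color(all_margin, image,
                                    config$reference_colors, config$detector)
      blobs <- blobs[match(paste(kept$y, kept$x), paste(blobs$y, blobs$x)), ,
                     drop = FALSE]
      blobs$aberration <- kept$aberration
    }
  }
  if (nrow(blobs) == 0L) return(empty_boxes())
  boxes <- do.call(rbind, lapply(seq_len(nrow(blobs)), function(i)
    blob_to_bbox(blobs[i, ], pad = config$pipeline$pad, image_size = d[1:2])))
  boxes <- boxes[order(boxes$y_min, boxes$x_min), , drop = FALSE]
  rownames(boxes) <- NULL
  boxes
}

# ---- Labelme I/O ---------------------------------------------------------

#' Export bounding boxes as a Labelme JSON document
#'
#' Writes the Labelme rectangle dialect: top-level `version`, `flags`,
#' `shapes`, `imagePath`, `imageData` (null), `imageHeight`, `imageWidth`;
#' each shape has `label`, two corner `points`, `shape_type` "rectangle",
#' `group_id` null and `flags`. Corner points are written exactly as the
#' package's half-open coordinates (`x_max` exclusive, written as-is); a
#' box's region, when known, is preserved in the shape's flags so the
#' round trip through [import_labelme()] is lossless.
#'
#' @param boxes box data.frame (see [blob_to_bbox()]).
#' @param image_path value for `imagePath`.
#' @param image_size `(H, W)` of the image.
#' @param file optional path; when given the JSON is written there.
#' @return the JSON string, invisibly when `file` is given.
#' @export
export_labelme <- function(boxes, image_path, image_size, file = NULL) {
  if (nrow(boxes) > 0L &&
      (any(boxes$x_min < 0) || any(boxes$y_min < 0) ||
       any(boxes$x_max > image_size[2]) || any(boxes$y_max > image_size[1])))
    stop("boxes exceed image bounds")
  empty_obj <- structure(list(), names = character(0))
  shapes <- lapply(seq_len(nrow(boxes)), function(i) {
    b <- boxes[i, ]
    flags <- if (!is.na(b$region)) list(region = b$region) else empty_obj
    list(label = b$label,
         points = list(c(b$x_min, b$y_min), c(b$x_max, b$y_max)),
         group_id = NULL, shape_type = "rectangle", flags = flags)
  })
  doc <- list(version = "5.0.1", flags = empty_obj, shapes = shapes,
              imagePath = image_path, imageData = NULL,
              imageHeight = image_size[1], imageWidth = image_size[2])
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, null = "null",
                           pretty = TRUE, digits = NA)
  if (!is.null(file)) {
    writeLines(json, file)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Import a Labelme JSON document as bounding boxes
#'
#' Reads rectangle shapes (two corner points in any order; corners are
#' normalized to min/max). Non-rectangle shapes are skipped with a
#' warning. A `region` flag on a shape, when present, is restored.
#'
#' @param x path to a Labelme JSON file, or a JSON string.
#' @return box data.frame.
#' @export
import_labelme <- function(x) {
  doc <- jsonlite::fromJSON(x, simplifyVector = FALSE)
  if (is.null(doc$shapes)) stop("not a Labelme document: missing `shapes`")
  skipped <- 0L
  rows <- lapply(doc$shapes, function(s) {
    if (!identical(s$shape_type, "rectangle") || length(s$points) != 2L) {
      skipped <<- skipped + 1L
      return(NULL)
    }
    p1 <- as.numeric(s$points[[1]]); p2 <- as.numeric(s$points[[2]])
    region <- if (!is.null(s$flags$region)) s$flags$region else NA_character_
    data.frame(x_min = min(p1[1], p2[1]), y_min = min(p1[2], p2[2]),
               x_max = max(p1[1], p2[1]), y_max = max(p1[2], p2[2]),
               label = if (is.null(s$label)) "prickle" else s$label,
               region = region, stringsAsFactors = FALSE)
  })
  if (skipped > 0L)
    warning(skipped, " non-rectangle shape(s) skipped")
  out <- do.call(rbind, rows)
  if (is.null(out)) empty_boxes() else out
}

# ---- grid search ---------------------------------------------------------

#' Grid-search specification
#'
#' One-parameter grids are built around the initial value: 11 factors 0.5,
#' 0.6, ..., 1.5 of the initial, integer-valued parameters rounded to the
#' nearest valid value and deduplicated.
#'
#' @param initial starting [blob_params()].
#' @param step_fraction grid step as a fraction of the initial value.
#' @param range_fractions `(lo, hi)` multiples of the initial value.
#' @param iou_threshold IoU at which predictions count as hits (the
#'   objective is detection F1 in the target region).
#' @param params_to_search character vector of parameter names to search
#'   (default: all numeric detector parameters, in declared order).
#' @param refs optional reference color set; when given (with the scene
#'   images), the chromatic filter participates and `max_aberration`
#'   becomes searchable.
#' @param max_cycles maximum full coordinate cycles (default 5).
#' @return a `grid_search_spec` list.
#' @export
grid_search_spec <- function(initial, step_fraction = 0.10,
                             range_fractions = c(0.50, 1.50),
                             iou_threshold = 0.3,
                             params_to_search = NULL, refs = NULL,
                             max_cycles = 5L) {
  if (!inherits(initial, "blob_params")) initial <- do.call(blob_params, initial)
  structure(list(initial = initial, step_fraction = step_fraction,
                 range_fractions = range_fractions,
                 iou_threshold = iou_threshold,
                 params_to_search = params_to_search, refs = refs,
                 max_cycles = max_cycles),
            class = "grid_search_spec")
}

GRID_PARAM_ORDER <- c("min_threshold", "max_threshold", "threshold_step",
                      "min_repeatability", "min_area", "max_area",
                      "min_circularity", "min_convexity",
                      "min_inertia_ratio", "max_aberration")
GRID_INTEGER_PARAMS <- c("min_threshold", "max_threshold", "threshold_step",
                         "min_repeatability", "min_area", "max_area")

grid_values <- function(name, initial_value, spec) {
  f <- seq(spec$range_fractions[1], spec$range_fractions[2],
           by = spec$step_fraction)
  v <- f * initial_value
  if (name %in% GRID_INTEGER_PARAMS) v <- round_half_up(v)
  if (name %in% c("threshold_step", "min_repeatability", "min_area"))
    v <- pmax(v, 1)
  if (name %in% c("min_circularity", "min_convexity", "min_inertia_ratio"))
    v <- pmin(v, 1)
  unique(v)
}

#' Coordinate-wise grid search of detector parameters
#'
#' Tunes one region's detector parameters against reference boxes.
#' A full Cartesian grid over all parameters is combinatorially infeasible
#' (11^10 points), so the search is coordinate-wise: parameters are cycled
#' in declared order; for each, its 11-value grid (others held fixed) is
#' scanned and the argmax of the objective is accepted (ties resolved
#' toward the value closest to the initial, then the smaller value);
#' cycling stops after a cycle with no change, or after `max_cycles`.
#' Because the initial value is on every grid, the returned objective is
#' never below the initial objective.
#'
#' The objective is detection F1 at `iou_threshold` against the reference
#' boxes whose centers fall in the target region, summed over scenes.
#'
#' @param scenes list of scenes; each a list with `image` (or `gray`),
#'   `mask`, and `boxes` (reference box data.frame).
#' @param region region group to tune: `"root_center"`, `"tip"` or
#'   `"margin"`.
#' @param spec a [grid_search_spec()].
#' @param fractions partition fractions used to delimit the region.
#' @return the tuned [blob_params()], with attributes `objective`,
#'   `initial_objective` and `n_evaluations`.
#' @export
grid_search_params <- function(scenes, region, spec,
                               fractions = partition_fractions()) {
  if (length(scenes) == 0L) stop("at least one scene is required")
  stopifnot(inherits(spec, "grid_search_spec"))
  region <- match.arg(region, c("root_center", "tip", "margin"))
  prep <- lapply(scenes, function(sc) {
    gray <- if (!is.null(sc$gray)) sc$gray else to_grayscale(sc$image)
    refined <- refine_mask(sc$mask)
    region_map <- partition_tongue(refined, fractions)
    grp <- box_center_group(sc$boxes, region_map)
    list(gray = gray, image = sc$image, region_map = region_map,
         gt = sc$boxes[grp == region, , drop = FALSE])
  })
  cache <- new.env(parent = emptyenv())
  n_eval <- 0L
  objective <- function(params) {
    key <- paste(unlist(params[GRID_PARAM_ORDER]), collapse = "|")
    hit <- cache[[key]]
    if (!is.null(hit)) return(hit)
    tp <- fp <- fn <- 0L
    for (sc in prep) {
      blobs <- detect_blobs(sc$gray, params)
      if (nrow(blobs) > 0L) {
        r <- round_half_up(blobs$y) + 1L; c_ <- round_half_up(blobs$x) + 1L
        inside <- r >= 1L & r <= nrow(sc$region_map) &
                  c_ >= 1L & c_ <= ncol(sc$region_map)
        code <- rep(0L, nrow(blobs))
        code[inside] <- sc$region_map[cbind(r[inside], c_[inside])]
        keep <- code != 0L & region_group(code) == region
        keep[is.na(keep)] <- FALSE
        blobs <- blobs[keep, , drop = FALSE]
      }
      if (nrow(blobs) > 0L && !is.null(spec$refs) && !is.null(sc$image)) {
        blobs$region <- if (region == "root_center") "center" else region
        blobs <- filter_blobs_by_color(
          blobs, sc$image, stats::setNames(list(spec$refs), region),
          stats::setNames(list(params), region))
      }
      pred <- if (nrow(blobs) == 0L) empty_boxes() else
        do.call(rbind, lapply(seq_len(nrow(blobs)), function(i)
          blob_to_bbox(blobs[i, ], pad = 1, image_size = dim(sc$gray))))
      m <- match_detections(sc$gt, pred, spec$iou_threshold)
      tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    }
    f1 <- if (2 * tp + fp + fn == 0L) 0 else 2 * tp / (2 * tp + fp + fn)
    cache[[key]] <- f1
    n_eval <<- n_eval + 1L
    f1
  }

  free <- spec$params_to_search %||% GRID_PARAM_ORDER
  free <- intersect(GRID_PARAM_ORDER, free)
  current <- spec$initial
  init_obj <- objective(current)
  best_obj <- init_obj
  for (cycle in seq_len(spec$max_cycles)) {
    changed <- FALSE
    for (p in free) {
      vals <- grid_values(p, spec$initial[[p]], spec)
      scores <- rep(NA_real_, length(vals))
      for (k in seq_along(vals)) {
        cand <- current
        cand[[p]] <- vals[k]
        ok <- tryCatch({ validate_blob_params(cand); TRUE },
                       error = function(e) FALSE)
        if (ok) scores[k] <- objective(cand)
      }
      if (all(is.na(scores))) next
      top <- max(scores, na.rm = TRUE)
      cand_idx <- which(!is.na(scores) & scores == top)
      # ties: closest to initial, then smaller value
      d0 <- abs(vals[cand_idx] - spec$initial[[p]])
      cand_idx <- cand_idx[order(d0, vals[cand_idx])]
      pick <- vals[cand_idx[1L]]
      if (!isTRUE(all.equal(pick, current[[p]]))) {
        current[[p]] <- pick
        changed <- TRUE
      }
      best_obj <- top
    }
    if (!changed) break
  }
  attr(current, "objective") <- best_obj
  attr(current, "initial_objective") <- init_obj
  attr(current, "n_evaluations") <- n_eval
  current
}

`%||%` <- function(a, b) if (is.null(a)) b else a
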