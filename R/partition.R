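#' Partition fractions
#'
#' The tongue is split by relative thickness: the top `f_root` of the
#' tongue's row extent is root, the bottom `f_tip` is tip, and within the
#' remaining middle band pixels whose distance to the nearer lateral contour
#' is at most `f_margin` times the row half-width are margin; the rest is
#' center.
#'
#' @param f_root,f_tip fractions of tongue length in (0,1), `f_root + f_tip
#'   < 1`.
#' @param f_margin fraction of the per-row half-width in (0,1).
#' @return a `partition_fractions` list.
#' @export
partition_fractions <- function(f_root = 0.25, f_tip = 0.20, f_margin = 0.20) {
  for (v in c(f_root, f_tip, f_margin))
    if (!is.numeric(v) || length(v) != 1L || v <= 0 || v >= 1)
      stop("fractions must be single numbers in (0, 1)")
  if (f_root + f_tip >= 1)
    stop("f_root + f_tip must be < 1")
  structure(list(f_root = f_root, f_tip = f_tip, f_margin = f_margin),
            class = "partition_fractions")
}

# Stop unless the mask is a single connected component (i.e. refined).
assert_refined <- function(mask) {
  assert_mask(mask)
  if (!any(mask)) stop("empty mask")
  n <- two_pass_label(mask, 8L)$n_components
  if (n != 1L)
    stop(sprintf("mask must be refined to a single component (found %d)", n))
  invisible(mask)
}

#' Reference frame of a refined tongue mask
#'
#' Builds the per-row description used by the partition: for every row
#' containing tongue pixels, the leftmost and rightmost tongue columns and
#' the lateral midpoint, smoothed along the tongue axis by a centered moving
#' average of window 5 rows (shrinking at the extent ends). Rows are the
#' parallel-line family: the acquisition device fixes head pose, so the
#' tongue axis is taken as the image vertical. All coordinates are 0-based
#' pixel indices.
#'
#' @param mask refined logical matrix (single connected component).
#' @return a `reference_frame` list: `rows` (0-based row indices of the
#'   extent), `left`, `right` (per-row span columns), `midline` (smoothed
#'   per-row midpoint), `length` (number of rows in the extent).
#' @export
compute_reference_frame <- function(mask) {
  assert_refined(mask)
  rows_any <- which(apply(mask, 1L, any))
  if (any(diff(rows_any) != 1L))
    stop("row extent has empty rows; mask is not refined")
  left <- right <- numeric(length(rows_any))
  for (i in seq_along(rows_any)) {
    cols <- which(mask[rows_any[i], ])
    left[i] <- cols[1L] - 1
    right[i] <- cols[length(cols)] - 1
  }
  raw_mid <- (left + right) / 2
  n <- length(raw_mid)
  mid <- vapply(seq_len(n), function(i) {
    j <- max(1L, i - 2L):min(n, i + 2L)
    mean(raw_mid[j])
  }, numeric(1))
  structure(list(rows = rows_any - 1L, left = left, right = right,
                 midline = mid, length = n),
            class = "reference_frame")
}

#' Partition a refined tongue mask into four areas
#'
#' Splits the tongue into root, center, tip and margin. With root at the top
#' image edge (device geometry; set `orientation = "root-bottom"` for
#' flipped acquisitions): rows within the top `f_root * length` of the row
#' extent are root, rows within the bottom `f_tip * length` are tip; in the
#' remaining middle band a pixel is margin when the distance from its center
#' to the nearer lateral contour edge (i.e. `min(c - left, right - c) +
#' 0.5`) is at most `f_margin` times the row half-width, and center
#' otherwise. The four regions cover the mask exactly.
#'
#' @param mask refined logical matrix.
#' @param fractions a [partition_fractions()] object.
#' @param orientation `"root-top"` (default) or `"root-bottom"`.
#' @return integer matrix over the region codes 0 (background), 1 (root),
#'   2 (center), 3 (tip), 4 (margin); class `region_map`.
#' @examples
#' m <- matrix(TRUE, 100, 40)
#' rm <- partition_tongue(m, partition_fractions(0.25, 0.20, 0.20))
#' table(region_name(rm))
#' @export
partition_tongue <- function(mask, fractions = partition_fractions(),
                             orientation = c("root-top", "root-bottom")) {
  orientation <- match.arg(orientation)
  if (!inherits(fractions, "partition_fractions"))
    fractions <- do.call(partition_fractions, as.list(fractions))
  if (orientation == "root-bottom") {
    flipped <- partition_tongue(mask[nrow(mask):1, , drop = FALSE], fractions)
    out <- flipped[nrow(flipped):1, , drop = FALSE]
    return(structure(out, class = c("region_map", "matrix")))
  }
  assert_refined(mask)
  frame <- compute_reference_frame(mask)
  L <- frame$length
  labels <- matrix(0L, nrow(mask), ncol(mask))
  for (i in seq_len(L)) {
    r <- frame$rows[i]                       # 0-based row
    cols <- which(mask[r + 1L, ]) - 1L       # 0-based columns
    rel_top <- i - 1L                        # rows above within extent
    rel_bot <- L - i
    if (rel_top < fractions$f_root * L) {
      labels[r + 1L, cols + 1L] <- REGION_CODES[["root"]]
    } else if (rel_bot < fractions$f_tip * L) {
      labels[r + 1L, cols + 1L] <- REGION_CODES[["tip"]]
    } else {
      lf <- frame$left[i]; rt <- frame$right[i]
      half_width <- (rt - lf + 1) / 2
      edge_dist <- pmin(cols - lf, rt - cols) + 0.5
      is_margin <- edge_dist <= fractions$f_margin * half_width
      labels[r + 1L, cols + 1L] <-
        ifelse(is_margin, REGION_CODES[["margin"]], REGION_CODES[["center"]])
    }
  }
  structure(labels, class = c("region_map", "matrix"))
}

#' Read and write region maps as PNG
#'
#' Region maps are stored as single-channel PNG holding the raw label values
#' 0-4 (so the image looks near-black; it is a label grid, not a picture).
#'
#' @param path file path.
#' @return `read_region_png()`: integer `region_map` matrix.
#' @export
read_region_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  structure(matrix(as.integer(round(a * 255)), nrow(a), ncol(a)),
            class = c("region_map", "matrix"))
}

#' @rdname read_region_png
#' @param region_map integer matrix over region codes 0-4.
#' @export
write_region_png <- function(region_map, path) {
  png::writePNG(matrix(as.numeric(region_map) / 255,
                       nrow(region_map), ncol(region_map)), path)
  invisible(path)
}
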