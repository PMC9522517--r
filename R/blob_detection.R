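#' Blob detector parameters
#'
#' Configuration of the multi-threshold spot detector for one tongue region.
#' The packaged defaults (see [default_config()]) carry one set for
#' root/center, one for tip and one for margin; root and center use tighter
#' shape and color bounds because coating and cracks make dark round-ish
#' false candidates more likely there.
#'
#' @param min_threshold,max_threshold gray levels in \[0,255\]; candidate
#'   binarizations are taken at `min_threshold, min_threshold + step, ...`
#'   strictly below `max_threshold` (half-open loop).
#' @param threshold_step positive gray-level step.
#' @param min_repeatability minimum number of thresholds at which a blob
#'   must reappear (any thresholds, not necessarily consecutive).
#' @param min_area,max_area component area bounds in pixels.
#' @param min_circularity,min_convexity,min_inertia_ratio shape-score lower
#'   bounds in \[0,1\] (see [shape_scores()]).
#' @param max_aberration upper bound on the redmean chromatic aberration to
#'   the nearest reference prickle color (used by
#'   [filter_blobs_by_color()], not by the gray-level detector itself).
#' @param min_dist_between_blobs grouping radius in pixels: per-threshold
#'   candidates whose centroids lie within this distance are considered the
#'   same blob.
#' @param polarity `"dark"` (default; candidates are pixels strictly below
#'   the threshold) or `"bright"` (strictly above).
#' @return a validated `blob_params` list.
#' @export
blob_params <- function(min_threshold = 60, max_threshold = 100,
                        threshold_step = 2, min_repeatability = 4,
                        min_area = 2, max_area = 40,
                        min_circularity = 0.4, min_convexity = 0.4,
                        min_inertia_ratio = 0.4, max_aberration = 100,
                        min_dist_between_blobs = 10,
                        polarity = c("dark", "bright")) {
  polarity <- match.arg(polarity)
  p <- list(min_threshold = min_threshold, max_threshold = max_threshold,
            threshold_step = threshold_step,
            min_repeatability = min_repeatability,
            min_area = min_area, max_area = max_area,
            min_circularity = min_circularity, min_convexity = min_convexity,
            min_inertia_ratio = min_inertia_ratio,
            max_aberration = max_aberration,
            min_dist_between_blobs = min_dist_between_blobs,
            polarity = polarity)
  validate_blob_params(p)
  structure(p, class = "blob_params")
}

validate_blob_params <- function(p) {
  num <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  stopifnot(num(p$min_threshold), num(p$max_threshold), num(p$threshold_step),
            num(p$min_repeatability), num(p$min_area), num(p$max_area),
            num(p$min_circularity), num(p$min_convexity),
            num(p$min_inertia_ratio), num(p$max_aberration),
            num(p$min_dist_between_blobs))
  if (p$min_threshold >= p$max_threshold)
    stop("min_threshold must be < max_threshold")
  if (p$min_threshold < 0 || p$max_threshold > 255)
    stop("thresholds must lie in [0, 255]")
  if (p$threshold_step <= 0) stop("threshold_step must be positive")
  if (p$min_repeatability < 1) stop("min_repeatability must be >= 1")
  if (p$min_area > p$max_area) stop("min_area must be <= max_area")
  for (b in c(p$min_circularity, p$min_convexity, p$min_inertia_ratio))
    if (b < 0 || b > 1) stop("shape-score bounds must lie in [0, 1]")
  if (p$max_aberration < 0) stop("max_aberration must be non-negative")
  if (!p$polarity %in% c("dark", "bright")) stop("invalid polarity")
  invisible(p)
}

#' Convert an RGB image to 8-bit luma
#'
#' Rec. 601 luma `0.299 R + 0.587 G + 0.114 B`, rounded half-up and clipped
#' to \[0,255\]. The spot detector works on this gray image; the color
#' information re-enters through the chromatic-aberration filter.
#'
#' @param image `H x W x 3` numeric array with 8-bit channel values.
#' @return integer `H x W` matrix in \[0,255\].
#' @export
to_grayscale <- function(image) {
  d <- dim(image)
  if (length(d) != 3L || d[3] != 3L)
    stop("`image` must be an H x W x 3 array")
  g <- 0.299 * image[, , 1L] + 0.587 * image[, , 2L] + 0.114 * image[, , 3L]
  g <- round_half_up(g)
  g[g < 0] <- 0; g[g > 255] <- 255
  matrix(as.integer(g), d[1], d[2])
}

# ---- shape scores --------------------------------------------------------

# Moore-neighbour boundary tracing on a padded logical window. Returns the
# traced boundary cycle length with diagonal steps counted sqrt(2).
# Neighbour order is clockwise (in image coordinates, y down):
# W, NW, N, NE, E, SE, S, SW. The tracer state is (pixel, backtrack
# direction); the walk is deterministic given the state, so the boundary
# cycle is the path between the first repeated state (an initial lead-in,
# when present, is not part of the boundary and is excluded).
moore_perimeter <- function(win) {
  offs <- rbind(c(0L, -1L), c(-1L, -1L), c(-1L, 0L), c(-1L, 1L),
                c(0L, 1L), c(1L, 1L), c(1L, 0L), c(1L, -1L))
  step_len <- sqrt(rowSums(offs^2))
  start <- which(t(win))[1L]                # raster order: topmost, leftmost
  nc <- ncol(win)
  cy <- (start - 1L) %/% nc + 1L
  cx <- (start - 1L) %% nc + 1L
  bdir <- 1L                                # backtrack direction: W
  total <- 0
  seen <- new.env(parent = emptyenv())
  max_steps <- 8L * (sum(win) * 4L + 16L)
  steps <- 0L
  repeat {
    key <- paste(cy, cx, bdir, sep = ",")
    prev_len <- seen[[key]]
    if (!is.null(prev_len)) return(total - prev_len)  # cycle closed
    seen[[key]] <- total
    found <- FALSE
    k <- bdir
    for (j in 1:8) {
      k <- k %% 8L + 1L                      # next clockwise neighbour
      ny <- cy + offs[k, 1L]; nx <- cx + offs[k, 2L]
      if (win[ny, nx]) { found <- TRUE; break }
    }
    if (!found) return(0)                    # isolated pixel
    total <- total + step_len[k]
    # new backtrack = direction from the new pixel toward the last empty
    # neighbour scanned (the one just before k, clockwise); ring-adjacent
    # cells are king-adjacent, so this is a valid direction
    prev_k <- (k - 2L) %% 8L + 1L
    ey <- cy + offs[prev_k, 1L]; ex <- cx + offs[prev_k, 2L]
    cy <- cy + offs[k, 1L]; cx <- cx + offs[k, 2L]
    bdir <- which(offs[, 1L] == ey - cy & offs[, 2L] == ex - cx)[1L]
    steps <- steps + 1L
    if (steps > max_steps) return(total)     # unreachable safety net
  }
}

# Shoelace area of a polygon given as x, y vectors.
polygon_area <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}

#' Shape scores of a connected pixel set
#'
#' Computes the scores the detector filters on. Area is the pixel count.
#' The perimeter is the length of the Moore-traced outer boundary path
#' through pixel centers (diagonal steps counted sqrt(2)) plus 4, the
#' Minkowski half-pixel correction that makes an `s x s` square measure
#' exactly `4 s` and a single pixel 4. Circularity is `4 pi A / P^2`
#' (clipped to \[0,1\]); convexity is the pixel count divided by the convex
#' hull area of the pixel-corner points; the inertia ratio is the ratio of
#' the smaller to the larger eigenvalue of the central second-moment matrix
#' of the pixel centers (1 for a single pixel).
#'
#' @param coords two-column matrix of 0-based pixel coordinates `(y, x)`,
#'   or a logical matrix whose `TRUE` pixels form the component.
#' @return named list: `area`, `perimeter`, `circularity`, `convexity`,
#'   `inertia_ratio`.
#' @examples
#' sq <- as.matrix(expand.grid(y = 0:9, x = 0:9))
#' shape_scores(sq)$circularity  # pi / 4
#' @export
shape_scores <- function(coords) {
  if (is.logical(coords) && is.matrix(coords)) {
    idx <- which(coords, arr.ind = TRUE)
    coords <- cbind(idx[, 1L] - 1L, idx[, 2L] - 1L)
  }
  if (!is.matrix(coords) || ncol(coords) != 2L || nrow(coords) == 0L)
    stop("`coords` must be a non-empty two-column (y, x) matrix")
  y <- coords[, 1L]; x <- coords[, 2L]
  area <- nrow(coords)

  # local window with a 1-pixel empty frame for the tracer
  y0 <- min(y); x0 <- min(x)
  win <- matrix(FALSE, max(y) - y0 + 3L, max(x) - x0 + 3L)
  win[cbind(y - y0 + 2L, x - x0 + 2L)] <- TRUE
  perimeter <- moore_perimeter(win) + 4

  circularity <- min(1, 4 * pi * area / perimeter^2)

  # convex hull over the 4 corners of every pixel
  cx <- c(x - 0.5, x + 0.5, x - 0.5, x + 0.5)
  cy <- c(y - 0.5, y - 0.5, y + 0.5, y + 0.5)
  h <- chull(cx, cy)
  hull_area <- polygon_area(cx[h], cy[h])
  convexity <- min(1, area / hull_area)

  if (area == 1L) {
    inertia <- 1
  } else {
    mu20 <- mean((x - mean(x))^2)
    mu02 <- mean((y - mean(y))^2)
    mu11 <- mean((x - mean(x)) * (y - mean(y)))
    disc <- sqrt((mu20 - mu02)^2 + 4 * mu11^2)
    lmax <- (mu20 + mu02 + disc) / 2
    lmin <- (mu20 + mu02 - disc) / 2
    inertia <- if (lmax <= 0) 1 else max(0, lmin) / lmax
  }
  list(area = area, perimeter = perimeter, circularity = circularity,
       convexity = convexity, inertia_ratio = inertia)
}

# ---- detection -----------------------------------------------------------

empty_blobs <- function() {
  data.frame(x = numeric(0), y = numeric(0), diameter = numeric(0),
             area = numeric(0), circularity = numeric(0),
             convexity = numeric(0), inertia_ratio = numeric(0),
             repeatability = integer(0), threshold = numeric(0),
             stringsAsFactors = FALSE)
}

# Per-threshold candidate extraction: label the binarized image, filter by
# area, score the survivors, filter by shape. Returns a data.frame of
# candidates (threshold, y, x, area, scores).
threshold_candidates <- function(gray, t, params) {
  cand <- if (params$polarity == "dark") gray < t else gray > t
  if (!any(cand)) return(NULL)
  lab <- cpp_two_pass_label(cand, 8L)
  n <- attr(lab, "n_components")
  if (n == 0L) return(NULL)
  h <- nrow(gray)
  px <- which(lab != 0L)
  labs <- lab[px]
  sizes <- tabulate(labs, nbins = n)
  keep <- which(sizes >= params$min_area & sizes <= params$max_area)
  if (length(keep) == 0L) return(NULL)
  sel <- labs %in% keep
  px <- px[sel]; labs <- labs[sel]
  yy <- (px - 1L) %% h          # 0-based row
  xx <- (px - 1L) %/% h         # 0-based col
  rows <- vector("list", length(keep))
  ri <- 0L
  for (grp in split(seq_along(px), labs)) {
    cy <- yy[grp]; cx <- xx[grp]
    s <- shape_scores(cbind(cy, cx))
    if (s$circularity < params$min_circularity) next
    if (s$convexity < params$min_convexity) next
    if (s$inertia_ratio < params$min_inertia_ratio) next
    ri <- ri + 1L
    rows[[ri]] <- c(t, mean(cy), mean(cx), s$area, s$circularity,
                    s$convexity, s$inertia_ratio)
  }
  if (ri == 0L) return(NULL)
  m <- do.call(rbind, rows[seq_len(ri)])
  colnames(m) <- c("threshold", "cy", "cx", "area", "circularity",
                   "convexity", "inertia_ratio")
  m
}

# Single-link grouping: connected components of the "centroid distance <=
# min_dist" relation, via union-find over the candidate list.
single_link_groups <- function(cy, cx, min_dist) {
  n <- length(cy)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  d2 <- min_dist^2
  for (i in seq_len(n - 1L)) {
    dy <- cy[(i + 1L):n] - cy[i]
    dx <- cx[(i + 1L):n] - cx[i]
    js <- which(dy * dy + dx * dx <= d2) + i
    for (j in js) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
    }
  }
  vapply(seq_len(n), find, integer(1))
}

#' Multi-threshold blob detection
#'
#' From-scratch multi-threshold spot detector. For every threshold `t` in
#' `min_threshold, min_threshold + step, ...` (strictly below
#' `max_threshold`) the gray image is binarized (dark polarity: pixel < t),
#' components are labeled with 8-connectivity, and components failing the
#' area or shape filters at that threshold are discarded. Surviving
#' candidates are grouped across thresholds by single-link transitive
#' closure on "centroid distance <= min_dist_between_blobs"; groups with at
#' least `min_repeatability` members become blobs. A blob's center is the
#' unweighted mean of its member centroids; its area and shape scores come
#' from the member at the median threshold (lower median for even counts);
#' its diameter is `2 sqrt(area / pi)`. Components touching the image
#' border are kept.
#'
#' @param gray integer matrix in \[0,255\] (see [to_grayscale()]).
#' @param params a [blob_params()] object.
#' @return data.frame of blobs sorted by `(y, x)`: columns `x`, `y`
#'   (0-based sub-pixel center), `diameter`, `area`, `circularity`,
#'   `convexity`, `inertia_ratio`, `repeatability`, `threshold` (the median
#'   member's threshold). Zero rows when nothing is found.
#' @export
detect_blobs <- function(gray, params) {
  if (!is.matrix(gray)) stop("`gray` must be a matrix")
  if (!inherits(params, "blob_params")) params <- do.call(blob_params, params)
  validate_blob_params(params)
  ts <- seq(params$min_threshold, params$max_threshold - 1e-9,
            by = params$threshold_step)
  cand <- do.call(rbind, lapply(ts, threshold_candidates,
                                gray = gray, params = params))
  if (is.null(cand) || nrow(cand) == 0L) return(empty_blobs())

  grp <- single_link_groups(cand[, "cy"], cand[, "cx"],
                            params$min_dist_between_blobs)
  out <- lapply(split(seq_len(nrow(cand)), grp), function(ix) {
    k <- length(ix)
    if (k < params$min_repeatability) return(NULL)
    m <- cand[ix, , drop = FALSE]
    m <- m[order(m[, "threshold"], m[, "cy"], m[, "cx"]), , drop = FALSE]
    med <- m[floor((k + 1) / 2), ]
    data.frame(x = mean(m[, "cx"]), y = mean(m[, "cy"]),
               diameter = 2 * sqrt(med[["area"]] / pi),
               area = med[["area"]], circularity = med[["circularity"]],
               convexity = med[["convexity"]],
               inertia_ratio = med[["inertia_ratio"]],
               repeatability = k, threshold = med[["threshold"]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out) || nrow(out) == 0L) return(empty_blobs())
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Region-partitioned blob detection
#'
#' Runs [detect_blobs()] once per parameter group on the full image and
#' keeps each blob only if it was detected under the parameters of the
#' region containing its rounded center; blobs whose center falls on
#' background are dropped. Because every blob is evaluated under exactly
#' its own region's parameters, duplicates across regions cannot occur.
#'
#' @param gray integer gray matrix.
#' @param region_map integer `region_map` aligned with `gray` (see
#'   [partition_tongue()]).
#' @param params_by_region named list of [blob_params()] with entries
#'   `root_center`, `tip`, `margin` (only groups present in the map are
#'   required).
#' @return blob data.frame as in [detect_blobs()] with an extra `region`
#'   column (`"root"`, `"center"`, `"tip"` or `"margin"`), sorted by
#'   `(y, x)`.
#' @export
detect_blobs_by_region <- function(gray, region_map, params_by_region) {
  if (!all(dim(gray) == dim(region_map)))
    stop("`region_map` must match `gray` in size")
  present_codes <- setdiff(sort(unique(as.integer(region_map))), 0L)
  groups <- unique(region_group(present_codes))
  missing <- setdiff(groups, names(params_by_region))
  if (length(missing) > 0L)
    stop("missing detector parameters for region group(s): ",
         paste(missing, collapse = ", "))
  res <- lapply(groups, function(g) {
    blobs <- detect_blobs(gray, params_by_region[[g]])
    if (nrow(blobs) == 0L) return(NULL)
    r <- round_half_up(blobs$y) + 1L
    c_ <- round_half_up(blobs$x) + 1L
    inside <- r >= 1L & r <= nrow(region_map) & c_ >= 1L & c_ <= ncol(region_map)
    code <- rep(0L, nrow(blobs))
    code[inside] <- region_map[cbind(r[inside], c_[inside])]
    keep <- code != 0L & region_group(code) == g
    keep[is.na(keep)] <- FALSE
    if (!any(keep)) return(NULL)
    blobs <- blobs[keep, , drop = FALSE]
    blobs$region <- region_name(code[keep])
    blobs
  })
  out <- do.call(rbind, res)
  if (is.null(out) || nrow(out) == 0L) {
    out <- empty_blobs()
    out$region <- character(0)
    return(out)
  }
  out <- out[order(out$y, out$x), , drop = FALSE]
  rownames(out) <- NULL
  out
}
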