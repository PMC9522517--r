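#' Redmean chromatic aberration between RGB colors
#'
#' Approximate perceptual (LAB-like) color difference computed directly in
#' RGB: with `rmean = (r1 + r2) / 2` and channel differences `dR, dG, dB`,
#' the aberration is
#' `sqrt((2 + rmean/256) dR^2 + 4 dG^2 + (2 + (255 - rmean)/256) dB^2)`.
#' Symmetric in its arguments and zero iff the colors are equal. This is
#' the "redmean" formula; it weighs red and blue differences by where the
#' pair sits on the red axis, mimicking human sensitivity without a true
#' CIE-LAB conversion.
#'
#' @param c1,c2 length-3 numeric vectors `(r, g, b)` in \[0,255\], or
#'   matrices with 3 columns (rows are compared pairwise; one argument may
#'   have a single row).
#' @return non-negative numeric vector of aberrations.
#' @examples
#' chromatic_aberration(c(255, 255, 255), c(0, 0, 0))  # ~764.83
#' @export
chromatic_aberration <- function(c1, c2) {
  c1 <- rgb_matrix(c1); c2 <- rgb_matrix(c2)
  if (nrow(c1) == 1L && nrow(c2) > 1L) c1 <- c1[rep(1L, nrow(c2)), , drop = FALSE]
  if (nrow(c2) == 1L && nrow(c1) > 1L) c2 <- c2[rep(1L, nrow(c1)), , drop = FALSE]
  if (nrow(c1) != nrow(c2)) stop("color row counts do not match")
  rmean <- (c1[, 1L] + c2[, 1L]) / 2
  dR <- c1[, 1L] - c2[, 1L]
  dG <- c1[, 2L] - c2[, 2L]
  dB <- c1[, 3L] - c2[, 3L]
  sqrt((2 + rmean / 256) * dR^2 + 4 * dG^2 + (2 + (255 - rmean) / 256) * dB^2)
}

rgb_matrix <- function(x) {
  if (is.null(dim(x))) {
    if (length(x) != 3L) stop("an RGB color needs exactly 3 channels")
    x <- matrix(x, 1L, 3L)
  }
  x <- as.matrix(x)
  if (ncol(x) != 3L) stop("RGB colors need exactly 3 columns")
  if (anyNA(x) || any(x < 0) || any(x > 255))
    stop("RGB channel values must lie in [0, 255]")
  x
}

#' Mean color of a blob's disk footprint
#'
#' Channel-wise mean over the pixels whose centers fall inside the disk of
#' radius `diameter / 2` around the blob center (at least the center pixel
#' is always included), rounded half-up.
#'
#' @param image `H x W x 3` array with 8-bit channel values.
#' @param blob one-row blob data.frame (or list) with `x`, `y`, `diameter`.
#' @return integer `(r, g, b)` vector.
#' @export
blob_mean_color <- function(image, blob) {
  d <- dim(image)
  h <- d[1]; w <- d[2]
  cxr <- round_half_up(blob$x) + 1L
  cyr <- round_half_up(blob$y) + 1L
  if (cxr < 1L || cxr > w || cyr < 1L || cyr > h)
    stop("blob center lies outside the image")
  radius <- blob$diameter / 2
  rr <- max(1L, ceiling(radius))
  ys <- max(1L, cyr - rr):min(h, cyr + rr)
  xs <- max(1L, cxr - rr):min(w, cxr + rr)
  dy <- (ys - 1) - blob$y
  dx <- (xs - 1) - blob$x
  inside <- outer(dy^2, dx^2, `+`) <= radius^2
  if (!any(inside)) inside[which(ys == cyr), which(xs == cxr)] <- TRUE
  sel <- which(inside, arr.ind = TRUE)
  py <- ys[sel[, 1L]]; px <- xs[sel[, 2L]]
  vapply(1:3, function(ch)
    as.integer(round_half_up(mean(image[cbind(py, px, ch)]))), integer(1))
}

#' Filter blobs by chromatic aberration to reference prickle colors
#'
#' The gray-level detector loses color; this filter brings it back. Each
#' blob's mean color (over its disk footprint) is compared against the
#' reference prickle colors of its region group, and the blob is kept iff
#' the minimum aberration over those references is at most the group's
#' `max_aberration`. Blob order is preserved.
#'
#' @param blobs blob data.frame with a `region` column (see
#'   [detect_blobs_by_region()]).
#' @param image `H x W x 3` array the blobs were detected on.
#' @param refs named list of reference color sets: for each region group
#'   (`root_center`, `tip`, `margin`) a matrix (or list of length-3
#'   vectors) of RGB reference colors.
#' @param params_by_region named list of [blob_params()] providing
#'   `max_aberration` per group.
#' @return the kept rows of `blobs`, with added columns `mean_r`, `mean_g`,
#'   `mean_b` and `aberration`.
#' @export
filter_blobs_by_color <- function(blobs, image, refs, params_by_region) {
  if (nrow(blobs) == 0L) {
    blobs$mean_r <- integer(0); blobs$mean_g <- integer(0)
    blobs$mean_b <- integer(0); blobs$aberration <- numeric(0)
    return(blobs)
  }
  if (is.null(blobs$region)) stop("blobs must carry a `region` column")
  groups <- region_group(match(blobs$region, names(REGION_CODES)) - 1L)
  need <- unique(groups)
  for (g in need) {
    if (is.null(refs[[g]]))
      stop("no reference colors configured for region group: ", g)
    if (is.null(params_by_region[[g]]))
      stop("no parameters configured for region group: ", g)
  }
  ref_mats <- lapply(refs, function(x) {
    if (is.list(x)) x <- do.call(rbind, x)
    rgb_matrix(x)
  })
  mc <- t(vapply(seq_len(nrow(blobs)),
                 function(i) blob_mean_color(image, blobs[i, ]), integer(3)))
  ab <- vapply(seq_len(nrow(blobs)), function(i) {
    min(chromatic_aberration(mc[i, ], ref_mats[[groups[i]]]))
  }, numeric(1))
  bound <- vapply(groups, function(g) params_by_region[[g]]$max_aberration,
                  numeric(1))
  blobs$mean_r <- mc[, 1L]; blobs$mean_g <- mc[, 2L]; blobs$mean_b <- mc[, 3L]
  blobs$aberration <- ab
  out <- blobs[ab <= bound, , drop = FALSE]
  rownames(out) <- NULL
  out
}
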