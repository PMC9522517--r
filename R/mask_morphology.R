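#' Binary mask validation
#'
#' A binary mask is a plain logical matrix (rows x cols) marking tongue
#' pixels. `assert_mask()` checks the representation and is called by every
#' operation that consumes a mask.
#'
#' @param mask logical matrix.
#' @param arg name used in error messages.
#' @return the mask, invisibly.
#' @export
assert_mask <- function(mask, arg = "mask") {
  if (!is.matrix(mask) || !is.logical(mask))
    stop(sprintf("`%s` must be a logical matrix", arg))
  if (nrow(mask) < 1L || ncol(mask) < 1L)
    stop(sprintf("`%s` has a zero-sized dimension", arg))
  if (anyNA(mask))
    stop(sprintf("`%s` contains NA", arg))
  invisible(mask)
}

#' Two-pass connected-component labeling
#'
#' Label the connected components of a binary mask with the classic two-pass
#' algorithm: a raster-order first pass assigns provisional labels and
#' records equivalences in a union-find structure (with path compression);
#' the second pass resolves equivalence classes and assigns final labels in
#' a single sweep. Final labels are consecutive integers `1..n_components`,
#' numbered by the raster-order position of each component's first pixel, so
#' the labeling is identical to a raster-order flood fill.
#'
#' @param mask logical matrix; `TRUE` = foreground.
#' @param connectivity 4 or 8 (default 8): neighbourhood defining
#'   connectedness.
#' @return a `label_grid`: list with `labels` (integer matrix, 0 =
#'   unlabeled) and `n_components`.
#' @examples
#' m <- matrix(FALSE, 10, 10)
#' m[1:2, 1:2] <- TRUE; m[9:10, 9:10] <- TRUE
#' two_pass_label(m)$n_components  # 2
#' @export
two_pass_label <- function(mask, connectivity = 8L) {
  assert_mask(mask)
  connectivity <- as.integer(connectivity)
  if (!connectivity %in% c(4L, 8L))
    stop("`connectivity` must be 4 or 8")
  lab <- cpp_two_pass_label(mask, connectivity)
  n <- attr(lab, "n_components")
  attr(lab, "n_components") <- NULL
  structure(list(labels = lab, n_components = n), class = "label_grid")
}

# Size of each component counted over `labels`; returns integer vector
# indexed by label.
component_sizes <- function(labels, n) {
  if (n == 0L) return(integer(0))
  tabulate(labels[labels > 0L], nbins = n)
}

# Largest component; ties resolved toward the smaller label, i.e. the
# component whose first raster-order pixel comes first.
largest_component <- function(sizes) which.max(sizes)

#' Refine a tongue mask to a single hole-free region
#'
#' Morphological post-processing for predicted tongue masks: keep only the
#' largest foreground component (8-connectivity), then relabel the
#' background (4-connectivity, with the image border treated as
#' background-adjacent so the whole exterior is one component) and keep only
#' the largest background component, converting every other background
#' component -- the interior holes -- to foreground. The result has exactly
#' one foreground and one background component and the operation is
#' idempotent. Ties on "largest" go to the component whose first
#' raster-order pixel comes first.
#'
#' @param mask logical matrix with at least one `TRUE` pixel.
#' @return logical matrix of the same size.
#' @examples
#' m <- matrix(FALSE, 12, 12)
#' m[3:10, 3:10] <- TRUE      # tongue
#' m[6:7, 6:7] <- FALSE       # interior hole
#' m[1, 12] <- TRUE           # speckle
#' r <- refine_mask(m)
#' sum(r)  # 64: hole filled, speckle gone
#' @export
refine_mask <- function(mask) {
  assert_mask(mask)
  if (!any(mask))
    stop("no tongue found: mask has no foreground pixel")
  fg <- two_pass_label(mask, 8L)
  keep <- largest_component(component_sizes(fg$labels, fg$n_components))
  core <- fg$labels == keep

  # background labeling on a TRUE-framed grid so the exterior is one
  # 4-connected component regardless of how the tongue touches the border
  h <- nrow(core); w <- ncol(core)
  padded <- matrix(TRUE, h + 2L, w + 2L)
  padded[2:(h + 1L), 2:(w + 1L)] <- !core
  bg <- two_pass_label(padded, 4L)
  inner <- bg$labels[2:(h + 1L), 2:(w + 1L), drop = FALSE]
  # sizes counted over real pixels only (the frame is virtual)
  sizes <- component_sizes(inner, bg$n_components)
  if (all(sizes == 0L)) return(matrix(TRUE, h, w))  # mask fills the image
  keep_bg <- largest_component(sizes)
  out <- inner != keep_bg
  dim(out) <- c(h, w)
  out
}

#' Read and write binary masks as PNG
#'
#' Masks travel as single-channel PNG with 0 = background and 255 =
#' foreground; on read, any nonzero value counts as foreground (only the
#' first channel of a multi-channel file is used).
#'
#' @param path file path.
#' @return `read_mask_png()`: logical matrix.
#' @export
read_mask_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3L) a <- a[, , 1L]
  a > 0
}

#' @rdname read_mask_png
#' @param mask logical matrix.
#' @export
write_mask_png <- function(mask, path) {
  assert_mask(mask)
  png::writePNG(matrix(as.numeric(mask), nrow(mask), ncol(mask)), path)
  invisible(path)
}
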