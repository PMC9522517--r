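#' Read and write 8-bit RGB images as PNG
#'
#' Images travel as `H x W x 3` integer arrays with values in \[0,255\].
#' Grayscale files are expanded to three identical channels; an alpha
#' channel, when present, is dropped.
#'
#' @param path file path.
#' @return `read_image_png()`: `H x W x 3` integer array.
#' @export
read_image_png <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 2L) a <- array(rep(a, 3L), c(dim(a), 3L))
  if (dim(a)[3] > 3L) a <- a[, , 1:3, drop = FALSE]
  out <- round_half_up(a * 255)
  storage.mode(out) <- "integer"
  out
}

#' @rdname read_image_png
#' @param image `H x W x 3` numeric array, 8-bit values.
#' @export
write_image_png <- function(image, path) {
  png::writePNG(array(pmin(1, pmax(0, as.numeric(image) / 255)),
                      dim(image)), path)
  invisible(path)
}
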