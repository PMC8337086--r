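# TIFF I/O for image stacks. Images on disk have row 1 at the top; they
# are flipped into the package's y-up frame on read and flipped back on
# write, so angle and angular-velocity sign conventions stay consistent.

#' Read a grayscale TIFF stack
#'
#' @param path file path
#' @return list of numeric matrices (y-up frame), one per page
#' @export
read_image_stack <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(pages)) pages <- list(pages)
  lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]
    flip_image(p)
  })
}

#' Write matrices as a 16-bit multi-page TIFF
#'
#' Rescales the stack's joint range to \[0, 1\] before writing (16-bit
#' quantization); a constant stack writes as zeros.
#'
#' @param images matrix or list of matrices (y-up frame)
#' @param path output file path
#' @return `path`, invisibly
#' @export
write_image_stack <- function(images, path) {
  if (is.matrix(images)) images <- list(images)
  rng <- range(unlist(lapply(images, range)))
  scale <- if (diff(rng) > 0) diff(rng) else 1
  pages <- lapply(images, function(m) flip_image((m - rng[1]) / scale))
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}
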