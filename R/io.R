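#' Read and write images
#'
#' 8-bit PNG or TIFF, chosen by file extension. Images are exchanged as
#' numeric matrices (grayscale) or H x W x 3 arrays (RGB) with intensities in
#' \[0, 255\]; masks as 0/1 matrices serialised to single-channel 0/255 PNG.
#'
#' @param path File path ending in `.png`, `.tif` or `.tiff`.
#' @param pixels Image to write.
#' @return `read_image()` returns the pixel matrix/array; writers return
#'   `path` invisibly.
#' @export
read_image <- function(path) {
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    png = png::readPNG(path),
    tif = ,
    tiff = tiff::readTIFF(path),
    stop(sprintf("unsupported image extension `%s`", ext))
  )
  if (length(dim(img)) == 3L && dim(img)[3] >= 3L) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (length(dim(img)) == 3L) {
    img <- img[, , 1]
  }
  img * 255
}

#' @rdname read_image
#' @export
write_image <- function(pixels, path) {
  ext <- tolower(tools::file_ext(path))
  img <- clip(pixels / 255, 0, 1)
  switch(ext,
    png = png::writePNG(img, path),
    tif = ,
    tiff = tiff::writeTIFF(img, path, bits.per.sample = 8L),
    stop(sprintf("unsupported image extension `%s`", ext))
  )
  invisible(path)
}

#' @rdname read_image
#' @param mask Binary matrix to serialise as 0/255 single-channel PNG.
#' @export
write_mask <- function(mask, path) {
  png::writePNG((mask != 0) * 1, path)
  invisible(path)
}

#' @rdname read_image
#' @export
read_mask <- function(path) {
  (png::readPNG(path) > 0.5) * 1L
}
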