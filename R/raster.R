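# RGBA raster images and binary pixel masks.
#
# Convention used throughout: origin at the top-left pixel, row-major
# storage, 0-based pixel coordinates when a coordinate is part of an API
# (blob centers); array indices in R remain 1-based.

#' Create an RGBA raster image
#'
#' @param pixels integer array `height x width x 4` with 8-bit channel
#'   values in 0..255 (R, G, B, A).
#' @return A `raster_image` object.
#' @export
new_raster_image <- function(pixels) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 4L) {
    stop("`pixels` must be a height x width x 4 array", call. = FALSE)
  }
  if (any(is.na(pixels)) || any(pixels < 0) || any(pixels > 255)) {
    stop("channel values must lie in 0..255", call. = FALSE)
  }
  storage.mode(pixels) <- "integer"
  structure(list(pixels = pixels), class = "raster_image")
}

#' @export
print.raster_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<raster_image> %d x %d px, RGBA\n", d[2], d[1]))
  invisible(x)
}

#' Create a binary pixel mask
#'
#' @param pixels logical matrix (`height x width`).
#' @return A `binary_mask` object (logical matrix with class attribute).
#' @export
new_binary_mask <- function(pixels) {
  if (!is.matrix(pixels) || !is.logical(pixels)) {
    stop("`pixels` must be a logical matrix", call. = FALSE)
  }
  pixels[is.na(pixels)] <- FALSE
  structure(pixels, class = c("binary_mask", "matrix", "array"))
}

#' Read a PNG file as a raster image
#'
#' @param path PNG file path.
#' @return A [new_raster_image()] object; grayscale and RGB inputs are
#'   expanded to RGBA with opaque alpha.
#' @export
read_png_raster <- function(path) {
  arr <- png::readPNG(path)
  if (length(dim(arr)) == 2L) arr <- array(arr, c(dim(arr), 1L))
  h <- dim(arr)[1]; w <- dim(arr)[2]; nc <- dim(arr)[3]
  out <- array(0L, c(h, w, 4L))
  if (nc == 1L) {
    for (ch in 1:3) out[, , ch] <- round(arr[, , 1] * 255)
    out[, , 4] <- 255L
  } else if (nc == 2L) {
    for (ch in 1:3) out[, , ch] <- round(arr[, , 1] * 255)
    out[, , 4] <- round(arr[, , 2] * 255)
  } else {
    for (ch in 1:3) out[, , ch] <- round(arr[, , ch] * 255)
    out[, , 4] <- if (nc >= 4L) round(arr[, , 4] * 255) else 255L
  }
  new_raster_image(out)
}

#' Write a raster image to PNG
#'
#' @param img a `raster_image`.
#' @param path output path.
#' @param dpi resolution metadata stamped into the PNG (default 300).
#' @return `path`, invisibly.
#' @export
write_png_raster <- function(img, path, dpi = 300) {
  stopifnot(inherits(img, "raster_image"))
  png::writePNG(img$pixels / 255, target = path, dpi = dpi)
  invisible(path)
}
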