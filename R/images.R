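#' RGB image container
#'
#' Wraps an H x W x 3 array of 8-bit intensities as the package's working
#' photographic representation. Coordinates are (row, col), origin top-left,
#' 0-based offsets in all neighborhood operations.
#'
#' @param pixels numeric or integer array, H x W x 3 (a single-channel H x W
#'   matrix is promoted to 3 identical channels), values in `[0, 255]`.
#' @param source optional provenance string (file path).
#' @return An object of class `rgb_image`: an integer H x W x 3 array with
#'   attributes `source`.
#' @export
rgb_image <- function(pixels, source = NULL) {
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be an H x W x 3 array (or an H x W matrix)")
  }
  if (anyNA(pixels)) stop("`pixels` contains NA")
  if (min(pixels) < 0 || max(pixels) > 255) {
    stop("pixel values must lie in [0, 255]")
  }
  px <- array(as.integer(round(pixels)), dim = dim(pixels))
  structure(px, class = "rgb_image", source = source)
}

#' @export
print.rgb_image <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<rgb_image %d x %d, range [%d, %d]>\n", d[1], d[2], min(x), max(x)))
  invisible(x)
}

#' Burn-depth label image
#'
#' Integer class map with codes 0 = healthy skin, 1 = superficial burn,
#' 2 = dermal (superficial-dermal) burn, 3 = deep-dermal / full-thickness burn.
#'
#' @param labels integer matrix with values in `{0, 1, 2, 3}`.
#' @return Object of class `label_image` (integer matrix).
#' @export
label_image <- function(labels) {
  if (!is.matrix(labels)) stop("`labels` must be a matrix")
  bad <- setdiff(unique(as.vector(labels)), 0:3)
  if (length(bad) > 0) {
    stop(sprintf("invalid label code(s): %s (allowed: 0,1,2,3)",
                 paste(bad, collapse = ", ")))
  }
  structure(matrix(as.integer(labels), nrow(labels), ncol(labels)),
            class = "label_image")
}

#' Names of the four depth classes, in label-code order
#' @return character vector `c("healthy","superficial","dermal","deep")`.
#' @export
burn_classes <- function() c("healthy", "superficial", "dermal", "deep")

#' @export
print.label_image <- function(x, ...) {
  tab <- tabulate(as.vector(x) + 1L, nbins = 4L)
  cat(sprintf("<label_image %d x %d: %s>\n", nrow(x), ncol(x),
              paste(sprintf("%s=%d", burn_classes(), tab), collapse = " ")))
  invisible(x)
}

#' Read an RGB photograph
#'
#' Reads PNG, TIFF or JPEG files as an [rgb_image]. Grayscale inputs are
#' promoted to three channels; an alpha channel, if present, is dropped.
#' 16-bit TIFF samples are rescaled to 8 bits (equivalent to a right-shift).
#'
#' @param path file path.
#' @return [rgb_image] with `source` set to `path`.
#' @export
read_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image: '%s' does not exist", path))
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    jpg  = ,
    jpeg = {
      img <- EBImage::readImage(path)
      # EBImage stores images x-major; transpose back to (row, col)
      a <- EBImage::imageData(img)
      if (length(dim(a)) == 2L) t(a) else aperm(a, c(2L, 1L, 3L))
    },
    stop(sprintf("unsupported image format: '%s'", ext))
  )
  if (is.null(dim(px))) stop(sprintf("not a decodable image: '%s'", path))
  if (length(dim(px)) == 3L && dim(px)[3] >= 3L) px <- px[, , 1:3, drop = FALSE]
  if (length(dim(px)) == 3L && dim(px)[3] == 1L) px <- px[, , 1L]
  # readers return [0,1] doubles regardless of bit depth; 65535 -> 255 falls out
  rgb_image(round(px * 255), source = path)
}

#' Write an RGB image as PNG
#'
#' @param image [rgb_image].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_image <- function(image, path) {
  stopifnot(inherits(image, "rgb_image"))
  png::writePNG(unclass(image) / 255, target = path)
  invisible(path)
}

#' Read a burn-depth label mask
#'
#' Single-channel PNG whose pixel values encode the class codes 0-3
#' (stored as `code/255` in the PNG).
#'
#' @param path PNG file path.
#' @return [label_image].
#' @export
read_label_mask <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read mask: '%s' does not exist", path))
  px <- png::readPNG(path)
  if (length(dim(px)) == 3L) {
    if (dim(px)[3] > 1L && any(px[, , 1] != px[, , 2])) {
      stop("label mask must be single-channel")
    }
    px <- px[, , 1L]
  }
  codes <- round(px * 255)
  bad <- setdiff(unique(as.vector(codes)), 0:3)
  if (length(bad) > 0) {
    stop(sprintf("label mask contains out-of-range value(s): %s",
                 paste(bad, collapse = ", ")))
  }
  label_image(codes)
}

#' Write a label mask as single-channel PNG
#'
#' @param labels [label_image].
#' @param path output path (`.png`).
#' @return `path`, invisibly.
#' @export
write_label_mask <- function(labels, path) {
  stopifnot(inherits(labels, "label_image"))
  png::writePNG(unclass(labels) / 255, target = path)
  invisible(path)
}
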