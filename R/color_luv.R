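# sRGB (D65) linear-RGB <-> XYZ matrices (IEC 61966-2-1 primaries)
.rgb2xyz <- matrix(c(
  0.4124564, 0.3575761, 0.1804375,
  0.2126729, 0.7151522, 0.0721750,
  0.0193339, 0.1191920, 0.9503041), 3, 3, byrow = TRUE)
.xyz2rgb <- solve(.rgb2xyz)
# D65 reference white (the matrix's own white, so neutral RGB maps to
# exactly u* = v* = 0) and its (u', v') chromaticity
.white_xyz <- c(X = sum(.rgb2xyz[1, ]), Y = sum(.rgb2xyz[2, ]),
                Z = sum(.rgb2xyz[3, ]))
.white_uv <- local({
  d <- .white_xyz[["X"]] + 15 * .white_xyz[["Y"]] + 3 * .white_xyz[["Z"]]
  c(u = 4 * .white_xyz[["X"]] / d, v = 9 * .white_xyz[["Y"]] / d)
})

.srgb_linearize <- function(c01) {
  ifelse(c01 <= 0.04045, c01 / 12.92, ((c01 + 0.055) / 1.055)^2.4)
}
.srgb_delinearize <- function(lin) {
  lin <- pmax(lin, 0)
  ifelse(lin <= 0.0031308, 12.92 * lin, 1.055 * lin^(1 / 2.4) - 0.055)
}

#' CIE L*u*v* image container
#'
#' The working color representation of the pipeline: luminance `L` in
#' `[0, 100]` plus chrominance planes `u` (green-to-red) and `v`
#' (blue-to-yellow). Neutral (gray) pixels have `u = v = 0`.
#'
#' @param L,u,v numeric matrices of a common size.
#' @param white white-point tag (only `"D65"` is produced by [rgb_to_luv]).
#' @return Object of class `luv_image`: list with elements `L`, `u`, `v`,
#'   `white`.
#' @export
luv_image <- function(L, u, v, white = "D65") {
  stopifnot(is.matrix(L), identical(dim(L), dim(u)), identical(dim(L), dim(v)))
  if (min(L) < -1e-9 || max(L) > 100 + 1e-9) stop("L must lie in [0, 100]")
  structure(list(L = L, u = u, v = v, white = white), class = "luv_image")
}

#' @export
print.luv_image <- function(x, ...) {
  cat(sprintf("<luv_image %d x %d (%s), L in [%.2f, %.2f]>\n",
              nrow(x$L), ncol(x$L), x$white, min(x$L), max(x$L)))
  invisible(x)
}

#' Convert an RGB photograph to CIE 1976 L*u*v*
#'
#' Per pixel: sRGB companding is inverted, linear RGB is mapped to XYZ under
#' the D65 white point, and XYZ to L*u*v*. Black pixels (Y = 0) get
#' `L = u = v = 0`.
#'
#' @param image [rgb_image].
#' @return [luv_image] of the same size.
#' @export
rgb_to_luv <- function(image) {
  stopifnot(inherits(image, "rgb_image"))
  d <- dim(image)
  rgb01 <- matrix(as.numeric(image), ncol = 3L) / 255
  xyz <- .srgb_linearize(rgb01) %*% t(.rgb2xyz)
  X <- xyz[, 1]; Y <- xyz[, 2]; Z <- xyz[, 3]
  yr <- Y / .white_xyz[["Y"]]
  L <- ifelse(yr > (6 / 29)^3, 116 * yr^(1 / 3) - 16, (29 / 3)^3 * yr)
  den <- X + 15 * Y + 3 * Z
  up <- ifelse(den > 0, 4 * X / den, .white_uv[["u"]])
  vp <- ifelse(den > 0, 9 * Y / den, .white_uv[["v"]])
  u <- 13 * L * (up - .white_uv[["u"]])
  v <- 13 * L * (vp - .white_uv[["v"]])
  luv_image(matrix(pmin(pmax(L, 0), 100), d[1], d[2]),
            matrix(u, d[1], d[2]), matrix(v, d[1], d[2]))
}

#' Convert an L*u*v* image back to 8-bit RGB
#'
#' Inverse of [rgb_to_luv]; out-of-gamut channels are clipped to `[0, 255]`.
#'
#' @param image [luv_image].
#' @return [rgb_image].
#' @export
luv_to_rgb <- function(image) {
  stopifnot(inherits(image, "luv_image"))
  d <- dim(image$L)
  L <- as.vector(image$L); u <- as.vector(image$u); v <- as.vector(image$v)
  Y <- ifelse(L > 8, .white_xyz[["Y"]] * ((L + 16) / 116)^3,
              .white_xyz[["Y"]] * L / (29 / 3)^3)
  nz <- L > 0
  up <- ifelse(nz, u / (13 * pmax(L, 1e-300)) + .white_uv[["u"]], .white_uv[["u"]])
  vp <- ifelse(nz, v / (13 * pmax(L, 1e-300)) + .white_uv[["v"]], .white_uv[["v"]])
  X <- Y * 9 * up / (4 * vp)
  Z <- Y * (12 - 3 * up - 20 * vp) / (4 * vp)
  lin <- cbind(X, Y, Z) %*% t(.xyz2rgb)
  rgb01 <- pmin(pmax(.srgb_delinearize(lin), 0), 1)
  rgb_image(array(round(rgb01 * 255), dim = c(d, 3L)))
}

#' Build a normalized 2-D Gaussian kernel
#'
#' Weights are proportional to `exp(-(x^2 + y^2) / (2 sigma^2))` evaluated at
#' integer offsets centered on 0 and normalized to sum to 1. The 5 x 5,
#' `sigma = 1.5` kernel is the preprocessing default.
#'
#' @param size odd integer >= 3, kernel side length.
#' @param sigma positive standard deviation, in pixels.
#' @return Object of class `gaussian_kernel`: list with `size`, `sigma`,
#'   `weights` (size x size, sums to 1).
#' @export
make_gaussian_kernel <- function(size = 5L, sigma = 1.5) {
  if (size < 3 || size %% 2 == 0) stop("`size` must be an odd integer >= 3")
  if (sigma <= 0) stop("`sigma` must be positive")
  off <- seq_len(size) - (size + 1) / 2
  w <- exp(-outer(off^2, off^2, "+") / (2 * sigma^2))
  structure(list(size = as.integer(size), sigma = sigma, weights = w / sum(w)),
            class = "gaussian_kernel")
}

# reflect index i (1-based, possibly out of range) into 1..n
.reflect_index <- function(i, n) {
  if (n == 1L) return(rep(1L, length(i)))
  p <- 2L * n - 2L
  j <- (i - 1L) %% p
  j <- ifelse(j < 0L, j + p, j)
  as.integer(ifelse(j >= n, p - j, j) + 1L)
}

#' Gaussian low-pass filter of one image plane
#'
#' 2-D convolution of a real-valued plane with a normalized Gaussian kernel,
#' using reflective boundary padding so constant regions are preserved up to
#' machine precision.
#'
#' @param plane numeric matrix, at least as large as the kernel.
#' @param kernel a [make_gaussian_kernel] object.
#' @return filtered matrix, same dimensions as `plane`.
#' @export
gaussian_filter <- function(plane, kernel = make_gaussian_kernel()) {
  stopifnot(is.matrix(plane), inherits(kernel, "gaussian_kernel"))
  k <- kernel$size
  h <- (k - 1L) %/% 2L
  if (nrow(plane) < k || ncol(plane) < k) stop("plane smaller than kernel")
  nr <- nrow(plane); nc <- ncol(plane)
  ridx <- .reflect_index(seq.int(1L - h, nr + h), nr)
  cidx <- .reflect_index(seq.int(1L - h, nc + h), nc)
  pad <- plane[ridx, cidx, drop = FALSE]
  out <- matrix(0, nr, nc)
  for (dr in seq_len(k)) {
    for (dc in seq_len(k)) {
      out <- out + kernel$weights[dr, dc] *
        pad[seq.int(dr, dr + nr - 1L), seq.int(dc, dc + nc - 1L), drop = FALSE]
    }
  }
  out
}

#' Gaussian-filter all three planes of an L*u*v* image
#'
#' Applies [gaussian_filter] independently to the L, u and v planes, the
#' standard noise-suppression step before enhancement and segmentation.
#'
#' @param image [luv_image].
#' @param kernel a [make_gaussian_kernel] object.
#' @return smoothed [luv_image].
#' @export
smooth_luv <- function(image, kernel = make_gaussian_kernel()) {
  stopifnot(inherits(image, "luv_image"))
  luv_image(gaussian_filter(image$L, kernel),
            gaussian_filter(image$u, kernel),
            gaussian_filter(image$v, kernel),
            white = image$white)
}
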