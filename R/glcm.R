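#' Quantize a real-valued plane to G gray levels
#'
#' Uniform binning of the plane's `[min, max]` range into `G` bins; a
#' constant plane maps to all zeros.
#'
#' @param plane numeric matrix.
#' @param G number of gray levels, >= 2.
#' @return integer matrix with values in `0..G-1`.
#' @export
quantize_levels <- function(plane, G = 8L) {
  stopifnot(is.matrix(plane), G >= 2)
  lo <- min(plane); hi <- max(plane)
  if (hi == lo) return(matrix(0L, nrow(plane), ncol(plane)))
  idx <- pmin(floor((plane - lo) / (hi - lo) * G), G - 1)
  matrix(as.integer(idx), nrow(plane), ncol(plane))
}

# (row, col) displacement for a co-occurrence angle
.glcm_offset <- function(angle, d) {
  switch(as.character(angle),
    "0"   = c(0L, d),
    "45"  = c(-d, d),
    "90"  = c(-d, 0L),
    "135" = c(-d, -d),
    stop("`angle` must be one of 0, 45, 90, 135"))
}

#' Gray-level co-occurrence matrix
#'
#' Normalized frequency `P(i, j)` of gray-level pairs at displacement `d`
#' along `angle` (degrees: 0 is rightward, 45 up-right, 90 up, 135 up-left,
#' in row/col image coordinates). With `symmetric = TRUE` reversed pairs are
#' counted too, making `P` symmetric.
#'
#' @param indices integer matrix of gray levels `0..G-1` (see
#'   [quantize_levels]).
#' @param d displacement, >= 1.
#' @param angle one of 0, 45, 90, 135.
#' @param symmetric count each pair in both directions (default TRUE).
#' @param G level count; default `max(indices) + 1`.
#' @return Object of class `glcm_matrix`: list with `p` (G x G, sums to 1),
#'   `levels`, `d`, `angle`, `symmetric`.
#' @export
compute_glcm <- function(indices, d = 1L, angle = 0, symmetric = TRUE,
                         G = max(indices) + 1L) {
  stopifnot(is.matrix(indices), d >= 1)
  off <- .glcm_offset(angle, as.integer(d))
  h <- nrow(indices); w <- ncol(indices)
  r0 <- max(1L, 1L - off[1]):min(h, h - off[1])
  c0 <- max(1L, 1L - off[2]):min(w, w - off[2])
  if (length(r0) < 1 || length(c0) < 1 || h <= abs(off[1]) || w <= abs(off[2])) {
    stop("image smaller than the requested offset")
  }
  i <- indices[r0, c0, drop = FALSE]
  j <- indices[r0 + off[1], c0 + off[2], drop = FALSE]
  counts <- matrix(tabulate(as.vector(i) * G + as.vector(j) + 1L, nbins = G * G),
                   G, G, byrow = TRUE)
  if (symmetric) counts <- counts + t(counts)
  structure(list(p = counts / sum(counts), levels = as.integer(G),
                 d = as.integer(d), angle = angle, symmetric = symmetric),
            class = "glcm_matrix")
}

#' GLCM contrast
#'
#' `sum_(i,j) (i - j)^2 P(i, j)`: large values flag sharp local intensity
#' changes (fine granularity).
#'
#' @param m [compute_glcm] result.
#' @return nonnegative real.
#' @export
glcm_contrast <- function(m) {
  stopifnot(inherits(m, "glcm_matrix"))
  G <- m$levels
  lv <- 0:(G - 1)
  sum(outer(lv, lv, "-")^2 * m$p)
}

#' GLCM correlation
#'
#' `sum_(i,j) (i - mu_i)(j - mu_j) P(i, j) / (sigma_i sigma_j)` with
#' marginal means and standard deviations; the linear dependency of paired
#' intensities. A degenerate matrix (zero marginal variance) returns 0 with
#' attribute `degenerate = TRUE`.
#'
#' @param m [compute_glcm] result.
#' @return real in `[-1, 1]`.
#' @export
glcm_correlation <- function(m) {
  stopifnot(inherits(m, "glcm_matrix"))
  G <- m$levels
  lv <- 0:(G - 1)
  pi_ <- rowSums(m$p); pj <- colSums(m$p)
  mu_i <- sum(lv * pi_); mu_j <- sum(lv * pj)
  s_i <- sqrt(sum((lv - mu_i)^2 * pi_)); s_j <- sqrt(sum((lv - mu_j)^2 * pj))
  if (s_i == 0 || s_j == 0) {
    return(structure(0, degenerate = TRUE))
  }
  sum(outer(lv - mu_i, lv - mu_j) * m$p) / (s_i * s_j)
}

# offset-averaged contrast and correlation of one plane
.plane_glcm_features <- function(plane, G, d) {
  idx <- quantize_levels(plane, G)
  angles <- c(0, 45, 90, 135)
  co <- numeric(4); cr <- numeric(4)
  for (a in seq_along(angles)) {
    m <- compute_glcm(idx, d = d, angle = angles[a], symmetric = TRUE, G = G)
    co[a] <- glcm_contrast(m)
    cr[a] <- as.numeric(glcm_correlation(m))
  }
  c(contrast = mean(co), correlation = mean(cr))
}

#' 10-value luminance-chroma texture feature vector
#'
#' For each source plane -- luminance `L` and chroma magnitude
#' `sqrt(u^2 + v^2)` -- computes GLCM contrast and correlation of the plane
#' and of its square (each averaged over the four offsets 0/45/90/135
#' degrees) plus the plane mean: 5 values per source, 10 in total.
#'
#' @param image [luv_image], at least `2 d` pixels in each dimension.
#' @param G gray levels for quantization (default 8).
#' @param d co-occurrence displacement (default 1).
#' @return named numeric vector of length 10:
#'   `src_{L,C}_{contrastL,corrL,contrastL2,corrL2,mean}`.
#' @export
feature_vector <- function(image, G = 8L, d = 1L) {
  stopifnot(inherits(image, "luv_image"))
  planes <- list(L = image$L, C = sqrt(image$u^2 + image$v^2))
  out <- numeric(0)
  for (nm in names(planes)) {
    p <- planes[[nm]]
    f1 <- .plane_glcm_features(p, G, d)
    f2 <- .plane_glcm_features(p^2, G, d)
    v <- c(f1[["contrast"]], f1[["correlation"]],
           f2[["contrast"]], f2[["correlation"]], mean(p))
    names(v) <- paste0("src_", nm, "_",
                       c("contrastL", "corrL", "contrastL2", "corrL2", "mean"))
    out <- c(out, v)
  }
  out
}

#' Texture feature table for a phantom dataset
#'
#' @param dataset [generate_dataset] result.
#' @param G,d passed to [feature_vector].
#' @param enhance apply [dce_enhance] with defaults before feature
#'   extraction (pipeline order), default TRUE.
#' @return data.frame: id, label, class and the 10 feature columns.
#' @export
dataset_features <- function(dataset, G = 8L, d = 1L, enhance = TRUE) {
  stopifnot(inherits(dataset, "phantom_dataset"))
  rows <- lapply(seq_along(dataset$phantoms), function(i) {
    luv <- rgb_to_luv(dataset$phantoms[[i]]$image)
    if (enhance) luv <- dce_enhance(luv)
    fv <- feature_vector(luv, G = G, d = d)
    cbind(data.frame(id = i, label = dataset$labels[i],
                     class = c("superficial", "dermal", "deep")[dataset$labels[i]]),
          as.data.frame(as.list(fv)))
  })
  do.call(rbind, rows)
}
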