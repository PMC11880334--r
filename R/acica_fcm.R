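#' Blind source separation of image channels (fixed-point ICA)
#'
#' Whitens the k channel rows and maximizes negentropy (logcosh contrast) by
#' the symmetric fixed-point iteration, estimating the unmixing matrix W of
#' the linear mixing model X = A S. Components are returned in decreasing
#' non-Gaussianity, each sign-fixed so its skewness is >= 0.
#'
#' @param planes k x n numeric matrix (k in 2:3 flattened channels, n >= 100
#'   pixels). Rows are centered internally.
#' @param seed integer seed for the random orthonormal start.
#' @param max_iter,tol fixed-point iteration controls.
#' @return Object of class `ica_model`: list with `mixing` (k x k estimate of
#'   A), `unmixing` (W, with `unmixing %*% mixing ~ I`), `sources` (k x n),
#'   `observed` (the centered input), `center` (row means), `converged`,
#'   and `identifiable` (FALSE, with a warning, when every extracted
#'   component is statistically indistinguishable from Gaussian).
#' @export
unmix_components <- function(planes, seed = 1L, max_iter = 200L, tol = 1e-6) {
  stopifnot(is.matrix(planes))
  k <- nrow(planes); n <- ncol(planes)
  if (!(k %in% 2:3)) stop("`planes` must have 2 or 3 rows")
  if (n < 100) stop("need at least 100 samples")
  ctr <- rowMeans(planes)
  xc <- planes - ctr
  cv <- tcrossprod(xc) / n
  eg <- eigen(cv, symmetric = TRUE)
  if (min(eg$values) < 1e-12 * max(eg$values)) {
    dep <- which.max(abs(eg$vectors[, k]))
    stop(sprintf("rank-deficient channel data: channel %d is linearly dependent", dep))
  }
  wh <- diag(1 / sqrt(eg$values), k) %*% t(eg$vectors)
  z <- wh %*% xc
  sym_decor <- function(W) {
    s <- eigen(tcrossprod(W), symmetric = TRUE)
    s$vectors %*% diag(1 / sqrt(s$values), k) %*% t(s$vectors) %*% W
  }
  W <- with_seed(seed, matrix(stats::rnorm(k * k), k, k))
  W <- sym_decor(W)
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    wz <- W %*% z
    g <- tanh(wz)
    gp <- rowMeans(1 - g^2)
    W1 <- sym_decor(tcrossprod(g, z) / n - diag(gp, k) %*% W)
    delta <- max(abs(abs(rowSums(W1 * W)) - 1))
    W <- W1
    if (delta < tol) { converged <- TRUE; break }
  }
  s <- W %*% z
  # order by negentropy proxy (logcosh contrast vs Gaussian), fix sign
  jg <- (rowMeans(log(cosh(s))) - 0.37456)^2
  identifiable <- max(jg) >= 1e-4 # Gaussian-only data scores O(1/n)
  if (!converged || !identifiable) {
    warning(paste("ICA components may be unidentifiable",
                  if (!identifiable) "(sources indistinguishable from Gaussian)"
                  else "(fixed-point iteration did not converge)"))
  }
  ord <- order(jg, decreasing = TRUE)
  W <- W[ord, , drop = FALSE]
  s <- s[ord, , drop = FALSE]
  sgn <- ifelse(rowMeans(s^3) < 0, -1, 1)
  W <- W * sgn
  s <- s * sgn
  unmixing <- W %*% wh
  structure(list(mixing = solve(unmixing), unmixing = unmixing, sources = s,
                 observed = xc, center = ctr, converged = converged,
                 identifiable = identifiable),
            class = "ica_model")
}

#' Pixel difference function (diagonal-neighbor map)
#'
#' `PDF(i, j) = |I(i, j) - I(i+1, j+1)|`: the absolute intensity difference
#' to the diagonal neighbor, highlighting boundaries between regions of
#' different burn severity.
#'
#' @param plane numeric matrix, at least 2 x 2.
#' @return (H-1) x (W-1) nonnegative matrix.
#' @export
pixel_pdf <- function(plane) {
  stopifnot(is.matrix(plane), nrow(plane) >= 2, ncol(plane) >= 2)
  h <- nrow(plane); w <- ncol(plane)
  abs(plane[-h, -w, drop = FALSE] - plane[-1, -1, drop = FALSE])
}

#' Mean intensity per labeled region
#'
#' `g[ii]` is the average intensity over pixels carrying region label `ii`;
#' the per-region contrast-agent concentration summary.
#'
#' @param plane numeric matrix.
#' @param labels integer matrix of the same size with labels `1..ncluster`.
#' @param ncluster number of regions; every label `1..ncluster` must occur.
#' @return numeric vector `g` of length `ncluster`.
#' @export
region_averages <- function(plane, labels, ncluster = max(labels)) {
  stopifnot(is.matrix(plane), identical(dim(plane), dim(labels)))
  g <- numeric(ncluster)
  for (ii in seq_len(ncluster)) {
    sel <- labels == ii
    if (!any(sel)) stop(sprintf("region %d is empty", ii))
    g[ii] <- mean(plane[sel])
  }
  g
}

#' Region-level contrast summary
#'
#' From the per-region averages `g` and the cluster centers: the squared
#' adjacent differences of `g` (region-level pixel-difference analogue), the
#' mean center `gbar`, and the contrast-concentration dispersion
#' `ica = sum((g - gbar)^2)`.
#'
#' @param g numeric vector of region averages (length >= 1).
#' @param centers numeric vector of cluster centers.
#' @return Object of class `acica_summary`: list with `g`, `region_pdf`
#'   (length `length(g) - 1`), `gbar`, `ica`.
#' @export
acica_summary <- function(g, centers) {
  stopifnot(length(g) >= 1, length(centers) >= 1)
  structure(list(
    g = g,
    region_pdf = if (length(g) > 1) diff(g)^2 else numeric(0),
    gbar = mean(centers),
    ica = sum((g - mean(centers))^2)
  ), class = "acica_summary")
}

# k-means++-style seeding on 1-D values (assumes RNG already seeded)
.seed_centers <- function(x, k) {
  ux <- unique(x)
  centers <- numeric(k)
  centers[1] <- ux[sample.int(length(ux), 1)]
  if (k > 1) {
    for (j in 2:k) {
      d2 <- vapply(ux, function(v) min((v - centers[1:(j - 1)])^2), numeric(1))
      if (sum(d2) == 0) {
        centers[j] <- ux[sample.int(length(ux), 1)]
      } else {
        centers[j] <- ux[sample.int(length(ux), 1, prob = d2)]
      }
    }
  }
  sort(centers)
}

#' Fuzzy C-means clustering of intensity values
#'
#' Bezdek's FCM on a vector of intensities: memberships
#' `u_ik = 1 / sum_j (d_ik / d_ij)^(2/(m-1))`, centers
#' `c_k = sum_i u_ik^m x_i / sum_i u_ik^m`, alternated until the largest
#' center shift falls below `tol` or `max_iter` is reached. Initialization
#' is a seeded k-means++-style draw on the distinct values, so runs are
#' reproducible. Centers are returned sorted ascending with memberships
#' reordered to match.
#'
#' @param values numeric vector (n >= ncluster distinct values).
#' @param ncluster number of clusters, >= 1.
#' @param m fuzzifier, > 1.
#' @param tol convergence tolerance on the maximum center shift.
#' @param max_iter iteration cap.
#' @param seed integer seed for center initialization.
#' @return Object of class `cluster_model`: list with `ncluster`, `centers`
#'   (ascending), `memberships` (n x ncluster, rows sum to 1), `m`,
#'   `objective_trace` (nonincreasing), `iterations`.
#' @export
fcm_cluster <- function(values, ncluster = 4L, m = 2, tol = 1e-5,
                        max_iter = 300L, seed = 1L) {
  x <- as.numeric(values)
  if (m <= 1) stop("fuzzifier `m` must be > 1")
  if (ncluster < 1) stop("`ncluster` must be >= 1")
  if (length(unique(x)) < ncluster) {
    stop("`ncluster` exceeds the number of distinct values")
  }
  centers <- with_seed(seed, .seed_centers(x, ncluster))
  ex <- 2 / (m - 1)
  memberships <- NULL
  trace <- numeric(0)
  update_u <- function(centers) {
    d <- abs(outer(x, centers, "-"))
    zero <- d < .Machine$double.eps
    d[zero] <- .Machine$double.eps
    inv <- d^(-ex)
    u <- inv / rowSums(inv)
    hit <- rowSums(zero) > 0
    if (any(hit)) {
      u[hit, ] <- zero[hit, , drop = FALSE] / rowSums(zero[hit, , drop = FALSE])
    }
    list(u = u, d = d)
  }
  for (it in seq_len(max_iter)) {
    uu <- update_u(centers)
    um <- uu$u^m
    trace <- c(trace, sum(um * uu$d^2))
    new_centers <- as.vector(crossprod(um, x)) / colSums(um)
    shift <- max(abs(new_centers - centers))
    centers <- new_centers
    memberships <- uu$u
    if (shift < tol) break
  }
  ord <- order(centers)
  uu <- update_u(centers[ord]) # memberships consistent with final centers
  structure(list(ncluster = as.integer(ncluster), centers = centers[ord],
                 memberships = uu$u, m = m, objective_trace = trace,
                 iterations = it),
            class = "cluster_model")
}

#' Hard cluster labels from fuzzy memberships
#'
#' Assigns each pixel the cluster of maximum membership (ties resolved to
#' the lower label). Labels are `1..ncluster` in ascending-center order.
#'
#' @param model [fcm_cluster] result.
#' @param shape integer `c(H, W)`; `prod(shape)` must equal the number of
#'   clustered values.
#' @return integer H x W matrix of labels.
#' @export
assign_levels <- function(model, shape) {
  stopifnot(inherits(model, "cluster_model"))
  u <- model$memberships
  if (prod(shape) != nrow(u)) stop("`shape` does not match clustered data")
  lab <- max.col(u, ties.method = "first")
  matrix(as.integer(lab), shape[1], shape[2])
}

#' ACICA + FCM segmentation of a luminance plane
#'
#' The complete region-analysis stage: FCM-cluster the plane's intensities,
#' derive hard region labels, then compute the region averages, region-level
#' squared differences, mean center `gbar` and dispersion `ica`.
#'
#' @param plane numeric matrix (typically the enhanced L plane).
#' @param ncluster cluster count (default 4: healthy + 3 burn depths).
#' @param ... passed to [fcm_cluster].
#' @return list with `labels` (H x W integer matrix, ascending-center
#'   order), `model` ([fcm_cluster] result), `summary` ([acica_summary]),
#'   `pdf` ([pixel_pdf] of the plane).
#' @export
acica_segment <- function(plane, ncluster = 4L, ...) {
  model <- fcm_cluster(as.vector(plane), ncluster = ncluster, ...)
  labels <- assign_levels(model, dim(plane))
  g <- region_averages(plane, labels, ncluster)
  list(labels = labels, model = model,
       summary = acica_summary(g, model$centers),
       pdf = pixel_pdf(plane))
}
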