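#' Parameters of the reference-region (RR) labeling algorithm
#'
#' @param zth dark-pixel discard threshold, intensity units in `[0, 255)`.
#' @param dth minimum separation between histogram-peak cluster centers
#'   (intensity units); closer peaks are merged.
#' @param qlevels quantization level count in `[8, 256]`.
#' @param th similarity threshold for first-pass labeling (intensity units);
#'   default `dth / 2`.
#' @return Object of class `rr_params`.
#' @export
rr_params <- function(zth = 10, dth = 16, qlevels = 64L, th = dth / 2) {
  if (zth < 0 || zth >= 255) stop("`zth` must lie in [0, 255)")
  if (dth <= 0) stop("`dth` must be positive")
  if (qlevels < 8 || qlevels > 256) stop("`qlevels` must lie in [8, 256]")
  if (th <= 0) stop("`th` must be positive")
  structure(list(zth = zth, dth = dth, qlevels = as.integer(qlevels), th = th),
            class = "rr_params")
}

#' Quantize a grayscale plane, discarding dark pixels
#'
#' Pixels below `zth` are masked as discarded; the rest are mapped onto
#' `qlevels` uniform bins over `[0, 255]` and replaced by their bin-center
#' value.
#'
#' @param plane integer-valued matrix in `[0, 255]`.
#' @param params [rr_params].
#' @return list with `quantized` (matrix; discarded pixels keep value 0) and
#'   `discarded` (logical matrix).
#' @export
quantize_discard <- function(plane, params = rr_params()) {
  stopifnot(is.matrix(plane))
  discarded <- plane < params$zth
  if (all(discarded)) stop("all pixels fall below `zth`: empty image")
  q <- params$qlevels
  width <- 256 / q
  bin <- pmin(floor(plane / width), q - 1)
  quantized <- (bin + 0.5) * width
  if (q == 256L) quantized <- bin # identity on 8-bit data
  quantized[discarded] <- 0
  list(quantized = quantized, discarded = discarded)
}

#' Histogram-peak cluster centers with distance merging
#'
#' Finds local maxima of the 256-bin histogram whose count exceeds the
#' acceptance threshold (mean count over nonzero bins), visits them in
#' decreasing count order, and merges any candidate closer than `dth` to an
#' already accepted center into it (count-weighted mean position). If no
#' local maximum clears the threshold the global maximum becomes the single
#' center.
#'
#' @param histogram integer vector of 256 counts for intensities 0..255.
#' @param params [rr_params].
#' @return Object of class `peak_centers`: list with `centers` (increasing
#'   intensities, pairwise gaps >= dth), `th` (the labeling similarity
#'   threshold from `params`), `count_threshold`, `histogram`, `fallback`
#'   (TRUE when the global-maximum fallback fired).
#' @export
find_peak_centers <- function(histogram, params = rr_params()) {
  stopifnot(length(histogram) == 256)
  counts <- as.numeric(histogram)
  vals <- 0:255
  keep <- vals >= params$zth
  if (sum(counts[keep]) == 0) stop("histogram empty above `zth`")
  counts[!keep] <- 0
  count_th <- mean(counts[counts > 0])
  # local maxima (plateau-tolerant: >= both neighbors, > at least one side overall)
  padded <- c(-Inf, counts, -Inf)
  is_max <- counts >= padded[1:256] & counts >= padded[3:258] & counts > 0
  cand <- which(is_max & counts >= count_th)
  fallback <- length(cand) == 0
  if (fallback) cand <- which.max(counts)
  cand <- cand[order(counts[cand], decreasing = TRUE)]
  centers <- numeric(0)
  weights <- numeric(0)
  for (b in cand) {
    pos <- vals[b]
    cnt <- counts[b]
    if (length(centers) > 0) {
      dist <- abs(centers - pos)
      j <- which.min(dist)
      if (dist[j] < params$dth) {
        centers[j] <- (centers[j] * weights[j] + pos * cnt) / (weights[j] + cnt)
        weights[j] <- weights[j] + cnt
        next
      }
    }
    centers <- c(centers, pos)
    weights <- c(weights, cnt)
  }
  # merged centers can drift toward each other; re-merge until all gaps >= dth
  repeat {
    ord <- order(centers)
    centers <- centers[ord]; weights <- weights[ord]
    if (length(centers) < 2) break
    gaps <- diff(centers)
    j <- which.min(gaps)
    if (gaps[j] >= params$dth) break
    merged <- (centers[j] * weights[j] + centers[j + 1] * weights[j + 1]) /
      (weights[j] + weights[j + 1])
    centers <- c(centers[-c(j, j + 1)], merged)
    weights <- c(weights[-c(j, j + 1)], weights[j] + weights[j + 1])
  }
  ord <- order(centers)
  structure(list(centers = centers[ord], th = params$th,
                 count_threshold = count_th, histogram = as.integer(histogram),
                 fallback = fallback),
            class = "peak_centers")
}

#' Label pixels by nearest histogram-peak center
#'
#' Two-pass nearest-center labeling: pass 1 labels each retained pixel with
#' its nearest center when `|I - center| <= th`; pass 2 raises `th` to the
#' largest minimum-center distance among still-unlabeled pixels and repeats,
#' so labeling is total. Discarded (dark) pixels and any degenerate
#' leftovers get label 1. Labels index centers in ascending-intensity order;
#' equidistant pixels take the lower-center label.
#'
#' @param plane grayscale matrix in `[0, 255]`.
#' @param centers [find_peak_centers] result.
#' @param params [rr_params].
#' @param discarded optional logical matrix of dark pixels to force to
#'   label 1.
#' @return Object of class `agent_image`: list with `labels` (H x W integer
#'   matrix, min >= 1), `counts` (pixels per label), `centers`, `th_final`.
#' @export
label_by_centers <- function(plane, centers, params = rr_params(),
                             discarded = NULL) {
  stopifnot(inherits(centers, "peak_centers"))
  cen <- centers$centers
  d <- abs(outer(as.vector(plane), cen, "-"))
  nearest <- max.col(-d, ties.method = "first") # tie -> lower center
  mind <- d[cbind(seq_along(nearest), nearest)]
  th <- centers$th
  lab <- ifelse(mind <= th, nearest, NA_integer_)
  if (anyNA(lab)) {
    th <- max(mind[is.na(lab)]) # raised threshold covers every pixel
    lab <- ifelse(mind <= th, nearest, 1L)
  }
  lab <- matrix(as.integer(lab), nrow(plane), ncol(plane))
  if (!is.null(discarded)) lab[discarded] <- 1L
  cnt <- tabulate(lab, nbins = length(cen))
  structure(list(labels = lab, counts = cnt, centers = cen, th_final = th),
            class = "agent_image")
}

#' Percentage of pixels carrying the agent labels
#'
#' @param img [label_by_centers] result.
#' @param agent_labels nonempty subset of the labels present in `img`.
#' @return percentage in `[0, 100]`.
#' @export
agent_percentage <- function(img, agent_labels) {
  stopifnot(inherits(img, "agent_image"))
  present <- seq_along(img$centers)
  if (length(agent_labels) == 0 || !all(agent_labels %in% present)) {
    stop("`agent_labels` must be a nonempty subset of the present labels")
  }
  100 * sum(img$counts[agent_labels]) / sum(img$counts)
}

#' Full RR-method segmentation of a grayscale plane
#'
#' Quantize with dark-pixel discard, build the 256-bin histogram of the
#' quantized plane, find merged peak centers, and produce the total label
#' image plus per-label percentages.
#'
#' @param plane grayscale matrix in `[0, 255]`.
#' @param params [rr_params].
#' @return list with `agent` ([label_by_centers] result), `centers`,
#'   `params`, `histogram_original`, `histogram_quantized`, `percent`
#'   (per-label percentages summing to 100).
#' @export
rr_segment <- function(plane, params = rr_params()) {
  qd <- quantize_discard(plane, params)
  hist_orig <- tabulate(pmin(pmax(round(plane), 0), 255) + 1L, nbins = 256L)
  keepv <- round(qd$quantized[!qd$discarded])
  hist_q <- tabulate(pmin(pmax(keepv, 0), 255) + 1L, nbins = 256L)
  centers <- find_peak_centers(hist_q, params)
  agent <- label_by_centers(qd$quantized, centers, params,
                            discarded = qd$discarded)
  pct <- 100 * agent$counts / sum(agent$counts)
  list(agent = agent, centers = centers, params = params,
       histogram_original = hist_orig, histogram_quantized = hist_q,
       percent = pct)
}
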