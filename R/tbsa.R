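#' Per-sample burned-surface percentages
#'
#' Treats the whole sample image as 100% and reports the exact pixel-share
#' of each depth class: `percent_c = 100 * count_c / total`. This is the
#' per-sample convention (the healthy class is always included so the
#' percentages conserve to 100); it is not the clinical rule-of-nines TBSA.
#'
#' @param labels [label_image].
#' @param sample_id optional sample identifier.
#' @return Object of class `tbsa_report`: list with `percent` (named over
#'   the 4 classes), `counts`, `total`, `sample_id`.
#' @export
tbsa_percentages <- function(labels, sample_id = NULL) {
  stopifnot(inherits(labels, "label_image"))
  total <- length(labels)
  if (total == 0) stop("empty label image")
  counts <- tabulate(as.vector(labels) + 1L, nbins = 4L)
  names(counts) <- burn_classes()
  structure(list(percent = 100 * counts / total, counts = counts,
                 total = total, sample_id = sample_id),
            class = "tbsa_report")
}

#' @export
print.tbsa_report <- function(x, ...) {
  cat(sprintf("<tbsa_report%s: %s>\n",
              if (is.null(x$sample_id)) "" else paste0(" ", x$sample_id),
              paste(sprintf("%s %.2f%%", names(x$percent), x$percent),
                    collapse = ", ")))
  invisible(x)
}

#' Per-depth luminance histograms with dark-pixel suppression
#'
#' For each depth class, the 256-bin histogram of the L plane (mapped to the
#' 0-255 scale) restricted to that class's pixels. Bins below `zth` are
#' zeroed (dark-pixel suppression) and histogram peaks closer than `dth` are
#' merged in the reported per-class peak list.
#'
#' @param image [luv_image].
#' @param labels [label_image] of the same size.
#' @param zth dark-bin threshold (0-255 scale).
#' @param dth peak-merging distance.
#' @return Object of class `depth_histogram`: list with `histograms` (4 x
#'   256 matrix, one row per class), `peaks` (list of merged peak positions
#'   per class), `empty` (classes whose histogram is empty after
#'   thresholding), `zth`, `dth`.
#' @export
depth_histograms <- function(image, labels, zth = 10, dth = 16) {
  stopifnot(inherits(image, "luv_image"), inherits(labels, "label_image"))
  if (!identical(dim(image$L), dim(unclass(labels)))) stop("shape mismatch")
  l255 <- pmin(pmax(round(image$L / 100 * 255), 0), 255)
  H <- matrix(0L, 4, 256, dimnames = list(burn_classes(), NULL))
  peaks <- vector("list", 4)
  names(peaks) <- burn_classes()
  empty <- character(0)
  params <- rr_params(zth = zth, dth = dth)
  for (k in 0:3) {
    sel <- unclass(labels) == k
    if (!any(sel)) {
      peaks[[k + 1]] <- numeric(0)
      next
    }
    h <- tabulate(l255[sel] + 1L, nbins = 256L)
    h[seq_len(256) - 1 < zth] <- 0L
    H[k + 1, ] <- h
    if (sum(h) == 0) {
      empty <- c(empty, burn_classes()[k + 1])
      peaks[[k + 1]] <- numeric(0)
    } else {
      peaks[[k + 1]] <- find_peak_centers(h, params)$centers
    }
  }
  structure(list(histograms = H, peaks = peaks, empty = empty,
                 zth = zth, dth = dth),
            class = "depth_histogram")
}

# class overlay colors: healthy gray, superficial yellow, dermal blue,
# deep red
.overlay_palette <- matrix(c(
  180, 180, 180,
  255, 215,   0,
   30,  80, 220,
  220,  30,  30), 4, 3, byrow = TRUE)

#' Write the per-sample report bundle
#'
#' Writes `report.json` (percentages, counts, per-class histogram peaks),
#' `overlay.png` (class-color-coded label overlay: yellow = superficial,
#' blue = dermal, red = deep, gray = healthy) and `pie.svg` (slice angles
#' proportional to the class percentages; each slice carries a
#' `data-angle` attribute in degrees).
#'
#' @param report [tbsa_percentages] result.
#' @param hist optional [depth_histograms] result.
#' @param overlay optional [label_image] to render.
#' @param dir output directory (created if missing).
#' @return named character vector of the written paths, invisibly.
#' @export
render_report <- function(report, hist = NULL, overlay = NULL, dir = ".") {
  stopifnot(inherits(report, "tbsa_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(json = file.path(dir, "report.json"))
  payload <- list(sample = report$sample_id,
                  percent = as.list(report$percent),
                  counts = as.list(report$counts))
  if (!is.null(hist)) payload$peaks <- hist$peaks
  jsonlite::write_json(payload, paths[["json"]], auto_unbox = TRUE,
                       digits = NA, null = "null")
  if (!is.null(overlay)) {
    stopifnot(inherits(overlay, "label_image"))
    lab <- unclass(overlay)
    px <- array(0, c(dim(lab), 3L))
    for (ch in 1:3) {
      px[, , ch] <- matrix(.overlay_palette[lab + 1L, ch], nrow(lab))
    }
    paths[["overlay"]] <- file.path(dir, "overlay.png")
    write_image(rgb_image(px), paths[["overlay"]])
  }
  paths[["pie"]] <- file.path(dir, "pie.svg")
  .write_pie_svg(report$percent, paths[["pie"]])
  invisible(paths)
}

# minimal SVG pie chart; slice angles sum to 360 degrees
.write_pie_svg <- function(percent, path, radius = 90) {
  angles <- percent / 100 * 360
  cx <- 100; cy <- 100
  start <- 0
  cols <- grDevices::rgb(.overlay_palette[, 1], .overlay_palette[, 2],
                         .overlay_palette[, 3], maxColorValue = 255)
  slices <- character(0)
  for (i in seq_along(angles)) {
    a <- angles[i]
    if (a <= 0) next
    if (a >= 360) {
      slices <- c(slices, sprintf(
        '<circle cx="%g" cy="%g" r="%g" fill="%s" data-class="%s" data-angle="%.6f"/>',
        cx, cy, radius, cols[i], names(percent)[i], a))
      start <- start + a
      next
    }
    a0 <- start * pi / 180; a1 <- (start + a) * pi / 180
    large <- as.integer(a > 180)
    slices <- c(slices, sprintf(
      '<path d="M %g %g L %.4f %.4f A %g %g 0 %d 1 %.4f %.4f Z" fill="%s" data-class="%s" data-angle="%.6f"/>',
      cx, cy, cx + radius * sin(a0), cy - radius * cos(a0),
      radius, radius, large, cx + radius * sin(a1), cy - radius * cos(a1),
      cols[i], names(percent)[i], a))
    start <- start + a
  }
  writeLines(c('<svg xmlns="http://www.w3.org/2000/svg" width="200" height="200">',
               slices, "</svg>"), path)
  invisible(path)
}
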