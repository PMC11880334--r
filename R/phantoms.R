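# run `expr` under a temporary RNG state seeded with `seed`
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Default phantom class palette
#'
#' Per-class mean RGB, channel standard deviation, and texture correlation
#' length (pixels; smaller = finer granularity, decreasing with burn depth).
#'
#' @return data.frame with one row per class (healthy, superficial, dermal,
#'   deep).
#' @export
phantom_palette <- function() {
  data.frame(
    class = burn_classes(),
    code = 0:3,
    r = c(205, 230, 200, 120),
    g = c(170, 160, 90, 40),
    b = c(150, 140, 80, 35),
    sd = c(8, 10, 12, 10),
    texture_scale = c(3.5, 2.5, 1.5, 0.8)
  )
}

#' Phantom specification
#'
#' Parameters of one synthetic burn image: canvas size, target burned-area
#' fractions for the three nested lesion rings (superficial outside, dermal,
#' deep inside), ellipse geometry, class color palette and noise texture
#' scales, and the seed that makes generation deterministic.
#'
#' @param size integer `c(H, W)`.
#' @param fractions named fractions for `superficial`, `dermal`, `deep`;
#'   each in `[0, 1]`, sum <= 1; the remainder is healthy skin.
#' @param center lesion center `c(row, col)`; default canvas center.
#' @param aspect ellipse axis ratio (minor/major) in (0, 1].
#' @param rotation lesion rotation, radians.
#' @param palette class palette as from [phantom_palette()].
#' @param geometry `"ellipse"` (nested rotated ellipses) or `"exact"`
#'   (row-major pixel runs giving exactly the requested fractions; used for
#'   worked-percentage constructions).
#' @param seed integer RNG seed.
#' @return Object of class `phantom_spec`.
#' @export
phantom_spec <- function(size = c(256L, 256L),
                         fractions = c(superficial = 0.22, dermal = 0.13,
                                       deep = 0.08),
                         center = NULL, aspect = 0.75, rotation = 0,
                         palette = phantom_palette(),
                         geometry = c("ellipse", "exact"),
                         seed = 1L) {
  geometry <- match.arg(geometry)
  fr <- c(superficial = 0, dermal = 0, deep = 0)
  fr[names(fractions)] <- fractions
  if (any(fr < 0) || any(fr > 1) || sum(fr) > 1) {
    stop("fractions must lie in [0,1] and sum to <= 1")
  }
  if (any(palette$r > 255 | palette$g > 255 | palette$b > 255) ||
      any(palette[c("r", "g", "b")] < 0)) stop("palette means must lie in [0,255]")
  if (is.null(center)) center <- (size + 1) / 2
  structure(list(size = as.integer(size), fractions = fr, center = center,
                 aspect = aspect, rotation = rotation, palette = palette,
                 geometry = geometry, seed = as.integer(seed)),
            class = "phantom_spec")
}

# separable reflect-padded Gaussian smoothing (texture synthesis helper)
.smooth_separable <- function(m, sigma) {
  if (sigma <= 0) return(m)
  h <- max(1L, ceiling(3 * sigma))
  w <- exp(-((-h):h)^2 / (2 * sigma^2))
  w <- w / sum(w)
  k <- length(w)
  pass <- function(x) { # filter along rows (dim 1)
    n <- nrow(x)
    idx <- .reflect_index(seq.int(1L - h, n + h), n)
    pad <- x[idx, , drop = FALSE]
    out <- matrix(0, n, ncol(x))
    for (j in seq_len(k)) {
      out <- out + w[j] * pad[seq.int(j, j + n - 1L), , drop = FALSE]
    }
    out
  }
  t(pass(t(pass(m))))
}

# correlated unit-variance noise field
.texture_field <- function(h, w, scale) {
  z <- matrix(stats::rnorm(h * w), h, w)
  s <- .smooth_separable(z, scale)
  sd0 <- stats::sd(as.vector(s))
  if (sd0 > 0) s / sd0 else s
}

# rasterize the nested-ellipse class mask for a phantom_spec
.phantom_mask <- function(spec) {
  h <- spec$size[1]; w <- spec$size[2]
  n <- h * w
  fr <- spec$fractions
  if (spec$geometry == "exact") {
    counts <- c(deep = round(fr[["deep"]] * n),
                dermal = round(fr[["dermal"]] * n),
                superficial = round(fr[["superficial"]] * n))
    lab <- rep(0L, n)
    pos <- 1L
    for (cls in c("deep", "dermal", "superficial")) {
      k <- counts[[cls]]
      if (k > 0) lab[pos:(pos + k - 1L)] <- match(cls, burn_classes()) - 1L
      pos <- pos + k
    }
    return(label_image(matrix(lab, h, w, byrow = TRUE)))
  }
  # nested ellipses: outer ring area = cumulative burned fraction
  rows <- matrix(seq_len(h), h, w)
  cols <- matrix(seq_len(w), h, w, byrow = TRUE)
  dy <- rows - spec$center[1]
  dx <- cols - spec$center[2]
  ca <- cos(spec$rotation); sa <- sin(spec$rotation)
  xr <- dx * ca + dy * sa
  yr <- -dx * sa + dy * ca
  lab <- matrix(0L, h, w)
  cum <- c(superficial = fr[["superficial"]] + fr[["dermal"]] + fr[["deep"]],
           dermal = fr[["dermal"]] + fr[["deep"]],
           deep = fr[["deep"]])
  for (cls in c("superficial", "dermal", "deep")) {
    area <- cum[[cls]] * h * w
    if (area <= 0) next
    a <- sqrt(area / (pi * spec$aspect)) # semi-major axis
    b <- a * spec$aspect
    if (2 * a > max(h, w) * 1.5) stop("lesion ellipse exceeds canvas")
    inside <- (xr / a)^2 + (yr / b)^2 <= 1
    lab[inside] <- match(cls, burn_classes()) - 1L
  }
  label_image(lab)
}

#' Generate one synthetic burn phantom
#'
#' Rasterizes the nested-ellipse class mask of `spec` and paints each class
#' with its palette mean plus correlated Gaussian noise at the class texture
#' scale (finer granularity for deeper burns). Fully deterministic in
#' `(spec, spec$seed)`.
#'
#' @param spec [phantom_spec].
#' @return list with `image` ([rgb_image]), `mask` ([label_image]) and
#'   `spec`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "phantom_spec"))
  mask <- .phantom_mask(spec)
  h <- spec$size[1]; w <- spec$size[2]
  px <- array(0, dim = c(h, w, 3L))
  with_seed(spec$seed, {
    for (k in seq_len(nrow(spec$palette))) {
      sel <- unclass(mask) == spec$palette$code[k]
      noise <- .texture_field(h, w, spec$palette$texture_scale[k])
      if (!any(sel)) next
      for (ch in 1:3) {
        mu <- spec$palette[[c("r", "g", "b")[ch]]][k]
        plane <- px[, , ch]
        plane[sel] <- mu + spec$palette$sd[k] * noise[sel]
        px[, , ch] <- plane
      }
    }
  })
  list(image = rgb_image(pmin(pmax(px, 0), 255)), mask = mask, spec = spec)
}

#' Generate a labeled phantom dataset
#'
#' Produces `n` phantoms whose dominant burn class (the classification
#' target, coded 1 = superficial, 2 = dermal, 3 = deep) follows `balance`.
#' The dominant class receives the largest lesion ring; geometry and exact
#' fractions vary per image, deterministically in `seed`.
#'
#' @param n number of phantoms (>= 9 when used for stratified splitting).
#' @param balance class proportions for (superficial, dermal, deep);
#'   default balanced.
#' @param seed integer seed.
#' @param size canvas size `c(H, W)`.
#' @return Object of class `phantom_dataset`: list with `phantoms` (list of
#'   [generate_phantom] results), `labels` (integer vector 1-3), `manifest`
#'   (data.frame: id, label, class, fractions, seed).
#' @export
generate_dataset <- function(n = 90L, balance = c(1, 1, 1) / 3, seed = 42L,
                             size = c(256L, 256L)) {
  if (n < 9) stop("`n` must be >= 9")
  if (length(balance) != 3 || any(balance < 0) || sum(balance) <= 0) {
    stop("`balance` must be 3 nonnegative proportions")
  }
  balance <- balance / sum(balance)
  counts <- floor(n * balance)
  rem <- n - sum(counts)
  if (rem > 0) {
    ord <- order(n * balance - counts, decreasing = TRUE)
    counts[ord[seq_len(rem)]] <- counts[ord[seq_len(rem)]] + 1L
  }
  if (any(counts == 0 & balance > 0) || any(counts < 3)) {
    stop("unachievable balance: every class needs >= 3 items")
  }
  labels <- rep.int(1:3, counts)
  cls_names <- c("superficial", "dermal", "deep")
  phantoms <- vector("list", n)
  rows <- vector("list", n)
  with_seed(seed, {
    labels <- sample(labels)
    seeds <- sample.int(.Machine$integer.max, n)
    for (i in seq_len(n)) {
      dom <- labels[i]
      fr <- stats::runif(3, 0.04, 0.09)
      fr[dom] <- stats::runif(1, 0.25, 0.35)
      names(fr) <- cls_names
      spec <- phantom_spec(
        size = size, fractions = fr,
        center = c(stats::runif(1, 0.4, 0.6) * size[1],
                   stats::runif(1, 0.4, 0.6) * size[2]),
        aspect = stats::runif(1, 0.6, 0.95),
        rotation = stats::runif(1, 0, pi),
        seed = seeds[i])
      phantoms[[i]] <- generate_phantom(spec)
      rows[[i]] <- data.frame(id = i, label = dom, class = cls_names[dom],
                              superficial = fr[["superficial"]],
                              dermal = fr[["dermal"]], deep = fr[["deep"]],
                              seed = seeds[i])
    }
  })
  structure(list(phantoms = phantoms, labels = labels,
                 manifest = do.call(rbind, rows), seed = seed),
            class = "phantom_dataset")
}

#' @export
print.phantom_dataset <- function(x, ...) {
  cat(sprintf("<phantom_dataset n=%d (superficial %d, dermal %d, deep %d), seed=%d>\n",
              length(x$labels), sum(x$labels == 1), sum(x$labels == 2),
              sum(x$labels == 3), x$seed))
  invisible(x)
}
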