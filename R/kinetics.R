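#' Plasma concentration curve
#'
#' Samples of the arterial plasma concentration C_p(t) on a strictly
#' increasing time grid starting at 0 (minutes). Units are arbitrary but
#' must be consistent between plasma and tissue curves.
#'
#' @param times numeric, strictly increasing from 0 (minutes).
#' @param cp nonnegative concentrations, same length.
#' @return Object of class `plasma_curve`.
#' @export
plasma_curve <- function(times, cp) {
  stopifnot(length(times) == length(cp), length(times) >= 2)
  if (times[1] != 0 || any(diff(times) <= 0)) {
    stop("`times` must be strictly increasing from 0")
  }
  if (any(cp < 0)) stop("`cp` must be nonnegative")
  structure(list(times = as.numeric(times), cp = as.numeric(cp)),
            class = "plasma_curve")
}

#' Synthesize a plasma input function
#'
#' `constant` gives C_p(t) = c; `biexponential` gives the usual two-decay
#' form a1*exp(-m1*t) + a2*exp(-m2*t).
#'
#' @param kind `"constant"` or `"biexponential"`.
#' @param grid time grid (minutes), strictly increasing from 0.
#' @param c constant level (kind = "constant").
#' @param a1,m1,a2,m2 biexponential amplitudes (>= 0) and decay rates.
#' @return [plasma_curve].
#' @export
generate_plasma_curve <- function(kind = c("constant", "biexponential"),
                                  grid = seq(0, 5, length.out = 301),
                                  c = 1, a1 = 3.99, m1 = 0.144,
                                  a2 = 4.78, m2 = 0.0111) {
  kind <- match.arg(kind)
  cp <- switch(kind,
    constant = {
      if (c < 0) stop("negative amplitude")
      rep(c, length(grid))
    },
    biexponential = {
      if (a1 < 0 || a2 < 0) stop("negative amplitude")
      a1 * exp(-m1 * grid) + a2 * exp(-m2 * grid)
    })
  plasma_curve(grid, cp)
}

#' Tissue concentration under the Tofts model
#'
#' Evaluates C_t(t) = Ktrans * integral_0^t C_p(tau) exp(-(Ktrans/ve)(t - tau)) dtau
#' by trapezoidal quadrature on the plasma curve's sample grid. `ktrans` is
#' the plasma-to-EES transfer constant (per minute); `ve` is the fractional
#' extracellular extravascular volume.
#'
#' @param ktrans transfer constant, >= 0 (1/min).
#' @param ve EES volume fraction in (0, 1].
#' @param plasma [plasma_curve].
#' @return Object of class `tissue_curve`: list with `times`, `ct`.
#' @export
tofts_concentration <- function(ktrans, ve, plasma) {
  stopifnot(inherits(plasma, "plasma_curve"))
  if (ktrans < 0) stop("`ktrans` must be >= 0")
  if (ve <= 0 || ve > 1) stop("`ve` must lie in (0, 1]")
  t <- plasma$times
  cp <- plasma$cp
  kep <- ktrans / ve
  n <- length(t)
  ct <- numeric(n)
  # recursive trapezoid: exact restatement of the full convolution quadrature
  for (i in 2:n) {
    dt <- t[i] - t[i - 1]
    decay <- exp(-kep * dt)
    ct[i] <- ct[i - 1] * decay +
      ktrans * dt / 2 * (cp[i - 1] * decay + cp[i])
  }
  structure(list(times = t, ct = pmax(ct, 0)), class = "tissue_curve")
}

#' Luminance enhancement driven by simulated contrast uptake
#'
#' The enhancement operator applied to the L plane: first a concave gamma
#' remap `L' = 100 (L/100)^gamma`, then an uptake-weighted lift
#' `L' <- L' + gain * U * (100 - L')` where `U = ct(eval_time)/max(ct)` from a
#' Tofts tissue curve (U = 1 when no curve is supplied). Chrominance planes
#' are untouched; the result is clipped to `[0, 100]`. The remap is monotone,
#' so pixel ordering in L is preserved.
#'
#' @param image [luv_image].
#' @param gain uptake gain, >= 0.
#' @param gamma exponent in (0, 1]; values < 1 brighten mid-tones.
#' @param uptake optional [tofts_concentration] result.
#' @param eval_time time (minutes) at which the uptake curve is read;
#'   required with `uptake`.
#' @return enhanced [luv_image].
#' @export
dce_enhance <- function(image, gain = 0.02, gamma = 0.85,
                        uptake = NULL, eval_time = NULL) {
  stopifnot(inherits(image, "luv_image"))
  if (gamma <= 0 || gamma > 1) stop("`gamma` must lie in (0, 1]")
  if (gain < 0) stop("`gain` must be >= 0")
  U <- 1
  if (!is.null(uptake)) {
    stopifnot(inherits(uptake, "tissue_curve"))
    if (is.null(eval_time)) stop("`eval_time` required when `uptake` is given")
    mx <- max(uptake$ct)
    U <- if (mx > 0) stats::approx(uptake$times, uptake$ct, eval_time, rule = 2)$y / mx else 0
  }
  L1 <- 100 * (pmax(image$L, 0) / 100)^gamma
  L1 <- L1 + gain * U * (100 - L1)
  luv_image(pmin(pmax(L1, 0), 100), image$u, image$v, white = image$white)
}

#' Distributional statistics of an intensity plane
#'
#' Mean, population standard deviation, Shannon entropy (bits) of the
#' 256-bin histogram, Fisher-Pearson skewness m3/m2^(3/2) and raw
#' (non-excess) kurtosis m4/m2^2. Planes on the `[0, 100]` luminance scale
#' are binned over `[0, 100]`; otherwise over `[0, 255]`.
#'
#' @param plane nonempty numeric matrix or vector.
#' @return Object of class `stats_summary`: list with `mean`, `std`,
#'   `entropy`, `skewness`, `kurtosis`, `degenerate` (TRUE for a constant
#'   plane, whose skewness/kurtosis are reported as 0).
#' @export
intensity_stats <- function(plane) {
  x <- as.numeric(plane)
  if (length(x) == 0) stop("empty plane")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  rng <- if (max(x) <= 100) 100 else 255
  bin <- pmin(pmax(floor(x / rng * 256), 0), 255)
  p <- tabulate(bin + 1L, nbins = 256L) / length(x)
  p <- p[p > 0]
  ent <- max(-sum(p * log2(p)), 0) # max() also clears IEEE negative zero
  degenerate <- m2 == 0
  structure(list(
    mean = m,
    std = sqrt(m2),
    entropy = ent,
    skewness = if (degenerate) 0 else mean((x - m)^3) / m2^1.5,
    kurtosis = if (degenerate) 0 else mean((x - m)^4) / m2^2,
    degenerate = degenerate
  ), class = "stats_summary")
}

#' @export
print.stats_summary <- function(x, ...) {
  cat(sprintf("mean %.4f  std %.4f  entropy %.4f bits  skew %.4f  kurt %.4f%s\n",
              x$mean, x$std, x$entropy, x$skewness, x$kurtosis,
              if (x$degenerate) "  (degenerate)" else ""))
  invisible(x)
}
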