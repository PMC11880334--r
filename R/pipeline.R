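.config_defaults <- function() {
  list(
    gaussian = list(size = 5L, sigma = 1.5),
    dce = list(gain = 0.02, gamma = 0.85, eval_time = 2.0, ktrans = 0.2,
               ve = 0.4),
    acica = list(ncluster = 4L, fuzzifier = 2, tol = 1e-5, max_iter = 300L,
                 seed = 7L, unmix = FALSE),
    rr = list(zth = 10, dth = 16, qlevels = 64L),
    glcm = list(levels = 8L, distance = 1L),
    model = list(kind = "fnn", epochs = 50L,
                 split_fractions = c(0.70, 0.15, 0.15), seed = 42L,
                 input_size = 32L),
    paths = list(out = ".")
  )
}

.config_bounds <- list(
  "gaussian.size" = function(v) v >= 3 && v %% 2 == 1,
  "gaussian.sigma" = function(v) v > 0,
  "dce.gain" = function(v) v >= 0,
  "dce.gamma" = function(v) v > 0 && v <= 1,
  "dce.eval_time" = function(v) v >= 0,
  "dce.ktrans" = function(v) v >= 0,
  "dce.ve" = function(v) v > 0 && v <= 1,
  "acica.ncluster" = function(v) v >= 1,
  "acica.fuzzifier" = function(v) v > 1,
  "acica.tol" = function(v) v > 0,
  "acica.max_iter" = function(v) v >= 1,
  "rr.zth" = function(v) v >= 0 && v < 255,
  "rr.dth" = function(v) v > 0,
  "rr.qlevels" = function(v) v >= 8 && v <= 256,
  "glcm.levels" = function(v) v >= 2,
  "glcm.distance" = function(v) v >= 1,
  "model.epochs" = function(v) v >= 1
)

#' Build and validate a pipeline configuration
#'
#' Starts from the documented defaults and merges `...` overrides (nested
#' lists mirroring the config sections). Unknown keys are rejected; numeric
#' fields are checked against their documented bounds. Configurations can
#' also be loaded from YAML with [read_config()].
#'
#' @param ... named section overrides, e.g.
#'   `pipeline_config(dce = list(gain = 0.5))`.
#' @return Object of class `pipeline_config` (nested list).
#' @export
pipeline_config <- function(...) {
  cfg <- .config_defaults()
  over <- list(...)
  if (length(over) > 0 && (is.null(names(over)) || any(names(over) == ""))) {
    stop("config overrides must be named")
  }
  for (sec in names(over)) {
    if (!sec %in% names(cfg)) stop(sprintf("unknown config section: '%s'", sec))
    if (!is.list(over[[sec]])) stop(sprintf("section '%s' must be a list", sec))
    for (key in names(over[[sec]])) {
      if (!key %in% names(cfg[[sec]])) {
        stop(sprintf("unknown config key: '%s.%s'", sec, key))
      }
      cfg[[sec]][[key]] <- over[[sec]][[key]]
    }
  }
  for (nm in names(.config_bounds)) {
    parts <- strsplit(nm, ".", fixed = TRUE)[[1]]
    v <- cfg[[parts[1]]][[parts[2]]]
    if (!.config_bounds[[nm]](v)) {
      stop(sprintf("config value out of bounds: %s = %s", nm, format(v)))
    }
  }
  structure(cfg, class = "pipeline_config")
}

#' Read a YAML pipeline configuration
#'
#' @param path YAML file whose top-level keys are config sections.
#' @return validated [pipeline_config].
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("config file '%s' does not exist", path))
  do.call(pipeline_config, yaml::read_yaml(path))
}

.new_runlog <- function() {
  data.frame(stage = character(0), elapsed = numeric(0),
             params = character(0), summary = character(0),
             timestamp = character(0))
}

.log_stage <- function(log, stage, t0, params, summary) {
  rbind(log, data.frame(
    stage = stage, elapsed = as.numeric(proc.time()[3] - t0),
    params = params, summary = summary,
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")))
}

#' Run the full burn-analysis pipeline on one image
#'
#' Stages, in order: RGB to L*u*v* conversion, Gaussian smoothing,
#' contrast-kinetic enhancement of the L plane (Tofts-uptake weighted),
#' ACICA+FCM segmentation, RR-method labeling, texture feature extraction,
#' depth classification (a trained model if supplied, otherwise the
#' dominant burn class of the segmentation), and the per-sample
#' burned-surface report. Every stage appends one record to the run log.
#' The pipeline is a pure function of `(config, image, model)`.
#'
#' @param config [pipeline_config].
#' @param image [rgb_image].
#' @param model optional trained [build_model] (kind `"fnn"`) for the
#'   classification stage.
#' @return list with `labels` ([label_image]), `segmentation`
#'   ([acica_segment] result), `rr` ([rr_segment] result), `features`
#'   (10-value vector), `predicted_class`, `tbsa` ([tbsa_percentages]),
#'   `log` (one row per stage).
#' @export
run_pipeline <- function(config, image, model = NULL) {
  stopifnot(inherits(config, "pipeline_config"), inherits(image, "rgb_image"))
  log <- .new_runlog()
  stage <- function(name, params, fn) {
    t0 <- proc.time()[3]
    out <- tryCatch(fn(), error = function(e) {
      stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
           call. = FALSE)
    })
    log <<- .log_stage(log, name, t0, params, attr(out, "log_summary") %||% "")
    out
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a

  luv <- stage("convert", "sRGB -> CIE L*u*v* (D65)", function() {
    out <- rgb_to_luv(image)
    kern <- make_gaussian_kernel(config$gaussian$size, config$gaussian$sigma)
    out <- smooth_luv(out, kern)
    structure(out, log_summary = sprintf("L range [%.1f, %.1f]",
                                         min(out$L), max(out$L)))
  })

  enhanced <- stage("enhance",
                    sprintf("gain=%.2f gamma=%.2f ktrans=%.2f ve=%.2f",
                            config$dce$gain, config$dce$gamma,
                            config$dce$ktrans, config$dce$ve), function() {
    plasma <- generate_plasma_curve("biexponential",
                                    grid = seq(0, max(2 * config$dce$eval_time, 1),
                                               length.out = 301))
    uptake <- tofts_concentration(config$dce$ktrans, config$dce$ve, plasma)
    out <- dce_enhance(luv, gain = config$dce$gain, gamma = config$dce$gamma,
                       uptake = uptake, eval_time = config$dce$eval_time)
    structure(out, log_summary = sprintf("mean L %.2f -> %.2f",
                                         mean(luv$L), mean(out$L)))
  })

  seg <- stage("acica", sprintf("ncluster=%d", config$acica$ncluster), function() {
    plane <- enhanced$L
    if (isTRUE(config$acica$unmix)) {
      ica <- unmix_components(rbind(as.vector(enhanced$L), as.vector(enhanced$u),
                                    as.vector(enhanced$v)),
                              seed = config$acica$seed)
      plane <- matrix(ica$sources[1, ], nrow(enhanced$L))
    }
    out <- acica_segment(plane, ncluster = config$acica$ncluster,
                         m = config$acica$fuzzifier, tol = config$acica$tol,
                         max_iter = config$acica$max_iter,
                         seed = config$acica$seed)
    structure(out, log_summary = sprintf(
      "centers [%s]; gbar %.2f; ica %.2f; region_pdf [%s]",
      paste(sprintf("%.1f", out$model$centers), collapse = ", "),
      out$summary$gbar, out$summary$ica,
      paste(sprintf("%.1f", out$summary$region_pdf), collapse = ", ")))
  })

  rr <- stage("rr", sprintf("zth=%g dth=%g q=%d", config$rr$zth, config$rr$dth,
                            config$rr$qlevels), function() {
    out <- rr_segment(enhanced$L / 100 * 255,
                      rr_params(config$rr$zth, config$rr$dth,
                                config$rr$qlevels))
    structure(out, log_summary = sprintf("%d centers; agent %% [%s]",
      length(out$centers$centers),
      paste(sprintf("%.1f", out$percent), collapse = ", ")))
  })

  feats <- stage("features", sprintf("G=%d d=%d", config$glcm$levels,
                                     config$glcm$distance), function() {
    out <- feature_vector(enhanced, G = config$glcm$levels,
                          d = config$glcm$distance)
    structure(out, log_summary = sprintf("contrast_L %.3f corr_L %.3f",
                                         out[["src_L_contrastL"]],
                                         out[["src_L_corrL"]]))
  })

  # FCM clusters are in ascending-L order; brighter tissue is shallower,
  # so the k cluster levels map onto the last k codes of (deep..healthy)
  k <- config$acica$ncluster
  code_map <- rev(seq(3, by = -1, length.out = min(k, 4)))
  if (k > 4) code_map <- c(rep(3, k - 4), code_map)
  labels <- label_image(matrix(code_map[seg$labels], nrow(seg$labels)))

  predicted <- stage("classify", sprintf("model=%s",
                                         if (is.null(model)) "dominant-class"
                                         else model$kind), function() {
    if (!is.null(model) && model$kind == "fnn") {
      probs <- .predict_probs(model, matrix(feats, nrow = 1), 1L)
      cls <- which.max(probs)
    } else {
      burned <- unclass(labels)[unclass(labels) > 0]
      cls <- if (length(burned) == 0) NA_integer_ else
        which.max(tabulate(burned, nbins = 3))
    }
    structure(cls, log_summary = sprintf("class %s",
      if (is.na(cls)) "none" else c("superficial", "dermal", "deep")[cls]))
  })

  tbsa <- stage("tbsa", "per-sample percentages", function() {
    out <- tbsa_percentages(labels, sample_id = attr(image, "source"))
    structure(out, log_summary = paste(sprintf("%s %.1f", names(out$percent),
                                               out$percent), collapse = " "))
  })

  list(labels = labels, segmentation = seg, rr = rr, features = feats,
       predicted_class = as.integer(predicted), tbsa = tbsa, log = log)
}
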