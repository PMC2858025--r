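#' Default pipeline configuration
#'
#' All tunable parameters of the segmentation and tracking pipeline with
#' their defaults, as a named list. Any subset can be overridden via
#' \code{...}; unknown names are rejected and every value is type- and
#' range-checked.
#'
#' Segmentation: \code{entropyWindow} (odd px, local-entropy window),
#' \code{entropyBins} (intensity histogram bins), \code{minRegionEntropy}
#' (bits; floor under the automatic threshold so that featureless background
#' never forms cell regions), \code{regionMethod} ("otsu" or "fixed"),
#' \code{regionThreshold} (bits, only for "fixed"), \code{closeRadius} (px,
#' morphological closing of the region mask), \code{minRegionArea} (px),
#' \code{detailWindow} (odd px, local-mean window of the detail
#' segmentation), \code{detailOffset} (intensity deviation from the local
#' mean marking cell detail), \code{minDetailArea} (px),
#' \code{mergeRadius} (px, single-linkage centroid merging).
#'
#' Tracking: \code{gate} (px, first monitoring threshold on the
#' track-to-measurement distance), \code{gateGrowth} (px of additional gate
#' per consecutive missed frame: while a track coasts, its position
#' uncertainty grows, so the acceptance region must widen for the track to
#' re-acquire its cell), \code{maxMissing} (coasting limit before a
#' track terminates), \code{mitosisGate} (px), \code{borderMargin} (px,
#' border zone for track initialization and leave-view classification),
#' \code{velDamping} (factor on the estimated velocity when extrapolating a
#' track's last determined position for association: cells maneuver --
#' contact deflections can turn the heading by far more than the typical
#' persistence suggests -- so full constant-velocity extrapolation
#' overshoots after a turn; damping the velocity bounds the association
#' error by roughly one step length in the worst case while still
#' anticipating most of the motion of fast straight-moving cells),
#' \code{accelSd} (px/frame^2, process-noise scale of the constant-velocity
#' model), \code{jitterSd} (px, per-coordinate measurement noise SD; default
#' is the pooled manual click jitter 5.14 px), \code{p0} (initial position
#' variance, px^2), \code{coastRInflation} (factor on R when correcting with
#' a coasted pseudo-measurement).
#'
#' Physics and statistics: \code{dtMin} (minutes per frame),
#' \code{pixelSizeUm} (um/px), \code{smoothWindow} (centered moving-average
#' window for track smoothing), \code{seed}.
#'
#' @param ... named overrides of any default.
#' @return named list with all configuration values.
#' @examples
#' cfg <- trackingConfig(gate = 30)
#' cfg$gate
#' @export
trackingConfig <- function(...) {
  cfg <- list(
    entropyWindow = 9L, entropyBins = 16L, minRegionEntropy = 1.5,
    regionMethod = "otsu", regionThreshold = NA_real_,
    closeRadius = 5L, minRegionArea = 100L,
    detailWindow = 15L, detailOffset = 0.05, minDetailArea = 5L,
    mergeRadius = 20,
    gate = 40, gateGrowth = 20, maxMissing = 3L, mitosisGate = 25,
    borderMargin = 30, velDamping = 0.6,
    accelSd = 1.0, jitterSd = 5.14, p0 = 26.4, coastRInflation = 100,
    dtMin = 15, pixelSizeUm = 1.5, smoothWindow = 5L, seed = 20100408L
  )
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)[1L]))
    over <- over[[1L]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown configuration keys: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  for (k in names(over)) {
    v <- over[[k]]
    if (k == "regionMethod") {
      if (!v %in% c("otsu", "fixed")) stop("regionMethod must be 'otsu' or 'fixed'")
      cfg[[k]] <- v
    } else {
      if (!is.numeric(v) || length(v) != 1L)
        stop("configuration value '", k, "' must be a single number",
             call. = FALSE)
      cfg[[k]] <- if (is.integer(cfg[[k]])) as.integer(v) else as.numeric(v)
    }
  }
  validateConfig(cfg)
  cfg
}

validateConfig <- function(cfg) {
  odd <- function(x) x %% 2L == 1L
  stopifnot(
    cfg$entropyWindow >= 3L, odd(cfg$entropyWindow),
    cfg$entropyBins >= 2L,
    cfg$minRegionEntropy >= 0,
    cfg$closeRadius >= 0L, cfg$minRegionArea >= 0L,
    cfg$detailWindow >= 3L, odd(cfg$detailWindow),
    cfg$detailOffset >= 0, cfg$minDetailArea >= 0L,
    cfg$mergeRadius > 0,
    cfg$gate > 0, cfg$gateGrowth >= 0, cfg$maxMissing >= 0L,
    cfg$mitosisGate > 0,
    cfg$borderMargin > 0, cfg$velDamping >= 0, cfg$velDamping <= 1,
    cfg$accelSd >= 0, cfg$jitterSd > 0, cfg$p0 > 0, cfg$coastRInflation >= 1,
    cfg$dtMin > 0, cfg$pixelSizeUm > 0,
    cfg$smoothWindow >= 3L, odd(cfg$smoothWindow)
  )
  if (cfg$regionMethod == "fixed" && is.na(cfg$regionThreshold))
    stop("regionThreshold must be set when regionMethod = 'fixed'",
         call. = FALSE)
  invisible(cfg)
}

#' Read / write a configuration file
#'
#' Flat \code{key = value} text format, one entry per line; blank lines and
#' lines starting with \code{#} are ignored. Unknown keys are rejected and
#' all values are validated as in [trackingConfig()].
#'
#' @param path file path.
#' @param cfg a configuration list from [trackingConfig()].
#' @return \code{readConfig} returns the validated configuration list;
#'   \code{writeConfig} returns \code{path} invisibly.
#' @examples
#' p <- tempfile(fileext = ".cfg")
#' writeConfig(trackingConfig(gate = 30), p)
#' readConfig(p)$gate
#' @export
readConfig <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  over <- list()
  for (ln in lines) {
    kv <- strsplit(ln, "=", fixed = TRUE)[[1L]]
    if (length(kv) != 2L)
      stop("malformed config line: '", ln, "'", call. = FALSE)
    key <- trimws(kv[1L]); val <- trimws(kv[2L])
    if (key == "regionMethod") {
      over[[key]] <- val
    } else {
      num <- suppressWarnings(as.numeric(val))
      if (is.na(num) && val != "NA")
        stop("non-numeric value for '", key, "': '", val, "'", call. = FALSE)
      over[[key]] <- num
    }
  }
  trackingConfig(over)
}

#' @rdname readConfig
#' @export
writeConfig <- function(cfg, path) {
  validateConfig(cfg)
  fmt <- vapply(names(cfg), function(k) {
    v <- cfg[[k]]
    paste0(k, " = ", if (is.character(v)) v else format(v, digits = 15))
  }, character(1))
  writeLines(fmt, path)
  invisible(path)
}
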