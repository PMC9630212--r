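#' Measurement configuration
#'
#' Bundles every free parameter of the CBO measurement protocol so that a
#' measurement is fully determined by an image plus a config. The defaults
#' reproduce the hands-free pipeline: automatic (Otsu) segmentation of the
#' log-scaled power plot, light spectrum smoothing, morphological cleanup and
#' a final convex hull.
#'
#' @param spectrum_gain Multiplicative gain applied to the log-magnitude
#'   spectrum before 0-255 quantization. Positive, valid range 1-400. The
#'   semi-automated protocol adjusts this (typically 70-200) until the power
#'   plot is well defined.
#' @param threshold_mode `"auto"` (Otsu's method on the non-zero spectrum
#'   values) or `"manual"` (a fixed cut on the 0-255 scale, mirroring manual
#'   segmentation).
#' @param manual_threshold Integer 0-255; required when
#'   `threshold_mode = "manual"`.
#' @param prefilter_sigma Standard deviation (in frequency bins) of the
#'   Gaussian smoothing applied to the scaled power plot before thresholding;
#'   0 disables. Smoothing suppresses single-structure spectral speckle so the
#'   segmented plot is contiguous.
#' @param min_area_fraction Connected components of the thresholded plot
#'   smaller than this fraction of the spectrum area are discarded.
#' @param smoothing_radius_px Disk radius for the morphological closing and
#'   opening that homogenize the segmented plot; 0 disables.
#' @param spike_removal_radius_px Disk radius of the opening that removes thin
#'   radial spikes (the automated surrogate for manual spike exclusion); 0
#'   disables.
#' @param apply_convex_hull Replace the cleaned plot by its filled convex
#'   hull (the protocol's final homogenization step).
#' @param window Apodization window applied before the FFT: `"none"` or
#'   `"hann"`. Hann suppresses the axis-aligned leakage cross caused by the
#'   periodic-extension discontinuity at the image edges.
#' @param grey_levels Working depth of the greyscale conversion, `"16bit"` or
#'   `"8bit"`. The measurement is invariant to this choice (the spectrum is
#'   renormalized), it only affects intermediate precision.
#' @param clip_percentile Percentile clipped at each end by the best-fit
#'   contrast stretch, in `[0, 5)`.
#' @param random_seed Optional integer recorded for provenance; the
#'   measurement pipeline itself is deterministic.
#'
#' @return An object of class `cbo_config` (a named list with a `digest`
#'   attribute).
#' @examples
#' cfg <- measurement_config(spectrum_gain = 150, window = "hann")
#' cfg$spectrum_gain
#' @export
measurement_config <- function(spectrum_gain = 100,
                               threshold_mode = c("auto", "manual"),
                               manual_threshold = NA_integer_,
                               prefilter_sigma = 1.5,
                               min_area_fraction = 5e-4,
                               smoothing_radius_px = 2L,
                               spike_removal_radius_px = 3L,
                               apply_convex_hull = TRUE,
                               window = c("none", "hann"),
                               grey_levels = c("16bit", "8bit"),
                               clip_percentile = 0.5,
                               random_seed = NA_integer_) {
  threshold_mode <- match.arg(threshold_mode)
  window <- match.arg(window)
  grey_levels <- match.arg(grey_levels)

  if (!is.numeric(spectrum_gain) || length(spectrum_gain) != 1 ||
      is.na(spectrum_gain) || spectrum_gain < 1 || spectrum_gain > 400) {
    abort("`spectrum_gain` must be a single number in [1, 400].",
          class = "cbo_error_invalid_config")
  }
  if (threshold_mode == "manual") {
    if (is.na(manual_threshold) || manual_threshold < 0 || manual_threshold > 255) {
      abort("`manual_threshold` (0-255) is required when `threshold_mode` is \"manual\".",
            class = "cbo_error_invalid_config")
    }
  }
  if (!is.numeric(min_area_fraction) || min_area_fraction <= 0 || min_area_fraction >= 1) {
    abort("`min_area_fraction` must lie in (0, 1).", class = "cbo_error_invalid_config")
  }
  if (smoothing_radius_px < 0 || spike_removal_radius_px < 0) {
    abort("morphology radii must be >= 0.", class = "cbo_error_invalid_config")
  }
  if (prefilter_sigma < 0) {
    abort("`prefilter_sigma` must be >= 0.", class = "cbo_error_invalid_config")
  }
  if (clip_percentile < 0 || clip_percentile >= 5) {
    abort("`clip_percentile` must lie in [0, 5).", class = "cbo_error_invalid_config")
  }

  cfg <- list(
    spectrum_gain = as.numeric(spectrum_gain),
    threshold_mode = threshold_mode,
    manual_threshold = as.integer(manual_threshold),
    prefilter_sigma = as.numeric(prefilter_sigma),
    min_area_fraction = as.numeric(min_area_fraction),
    smoothing_radius_px = as.integer(smoothing_radius_px),
    spike_removal_radius_px = as.integer(spike_removal_radius_px),
    apply_convex_hull = isTRUE(apply_convex_hull),
    window = window,
    grey_levels = grey_levels,
    clip_percentile = as.numeric(clip_percentile),
    random_seed = as.integer(random_seed)
  )
  class(cfg) <- "cbo_config"
  attr(cfg, "digest") <- config_digest(cfg)
  cfg
}

#' Hash of a canonicalized measurement configuration
#'
#' The digest changes iff any configuration field changes; it is stored with
#' every measurement so manual parameter choices (gain, threshold) remain
#' auditable.
#'
#' @param config A [measurement_config()] object.
#' @return A 12-character hexadecimal string.
#' @export
config_digest <- function(config) {
  stopifnot(inherits(config, "cbo_config"))
  fields <- unclass(config)
  fields <- fields[order(names(fields))]
  canon <- jsonlite::toJSON(fields, auto_unbox = TRUE, digits = NA, null = "null")
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp), add = TRUE)
  writeLines(canon, tmp)
  unname(substr(tools::md5sum(tmp), 1L, 12L))
}

#' Load a measurement configuration from YAML or JSON
#'
#' Missing keys take the [measurement_config()] defaults; unknown keys are
#' rejected so typos cannot silently change a measurement.
#'
#' @param path Path to a `.yaml`/`.yml`/`.json` file, or `NULL`/`""` for the
#'   all-defaults configuration.
#' @return A `cbo_config` object.
#' @export
load_config <- function(path = NULL) {
  if (is.null(path) || !nzchar(path)) {
    return(measurement_config())
  }
  if (!file.exists(path)) {
    abort(paste0("config file not found: ", path), class = "cbo_error_invalid_config")
  }
  raw <- tryCatch(
    if (grepl("\\.json$", path, ignore.case = TRUE)) {
      jsonlite::fromJSON(path, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(path)
    },
    error = function(e) {
      abort(paste0("could not parse config file: ", conditionMessage(e)),
            class = "cbo_error_invalid_config")
    }
  )
  if (!is.list(raw)) {
    abort("config file must contain a key-value mapping.",
          class = "cbo_error_invalid_config")
  }
  allowed <- names(formals(measurement_config))
  unknown <- setdiff(names(raw), allowed)
  if (length(unknown) > 0) {
    abort(paste0("unknown config key(s): ", paste(unknown, collapse = ", ")),
          class = "cbo_error_invalid_config")
  }
  do.call(measurement_config, raw)
}

#' @export
print.cbo_config <- function(x, ...) {
  cat("<cbo_config> digest:", attr(x, "digest"), "\n")
  for (nm in names(x)) {
    cat(sprintf("  %-24s %s\n", nm, format(x[[nm]])))
  }
  invisible(x)
}
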