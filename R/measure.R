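#' Measure the CBO index of a grey image
#'
#' Runs the Fourier half of the protocol on an already-greyscale image:
#' best-fit contrast, power plot, segmentation, cleanup, spike removal, axis
#' measurement. [measure_micrograph()] wraps this with the greyscale
#' conversion and metadata handling.
#'
#' @param grey A [grey_image()].
#' @param config A [measurement_config()].
#' @return A `cbo_orientation` object: `index`, `axes`, `threshold_used`,
#'   `spectrum_gain`, `config` and `config_digest`.
#' @export
measure_grey <- function(grey, config = measurement_config()) {
  stopifnot(inherits(grey, "cbo_grey"), inherits(config, "cbo_config"))
  g <- best_fit_contrast(grey, clip_percentile = config$clip_percentile)
  ps <- compute_power_spectrum(g, gain = config$spectrum_gain,
                               window = config$window,
                               prefilter_sigma = config$prefilter_sigma)
  sm <- segment_spectrum(ps, mode = config$threshold_mode,
                         manual_threshold = config$manual_threshold)
  sm <- clean_mask(sm, min_area_fraction = config$min_area_fraction,
                   smoothing_radius_px = config$smoothing_radius_px,
                   apply_convex_hull = FALSE)
  sm <- split_spikes(sm, spike_removal_radius_px = config$spike_removal_radius_px,
                     min_area_fraction = config$min_area_fraction)
  if (config$apply_convex_hull) {
    sm <- spectrum_mask(convex_hull_mask(sm$mask),
                        threshold_used = sm$threshold_used, dc = sm$dc)
  }
  axes <- measure_axes(sm)
  structure(
    list(index = orientation_index(axes),
         axes = axes,
         threshold_used = sm$threshold_used,
         spectrum_gain = config$spectrum_gain,
         mask_area_px = sm$area_px,
         config = config,
         config_digest = attr(config, "digest")),
    class = "cbo_orientation"
  )
}

#' Measure the CBO index of a micrograph
#'
#' Composes the full protocol: greyscale conversion, best-fit contrast, FFT
#' power plot with gain scaling, (auto or manual) segmentation of the central
#' frequencies, area filter, hole filling, smoothing, spike removal, convex
#' hull, and the minor/major caliper axis ratio. Deterministic for a fixed
#' image and configuration.
#'
#' @param img A `cbo_micrograph`.
#' @param config A [measurement_config()].
#' @return A `cbo_orientation` object.
#' @export
measure_micrograph <- function(img, config = measurement_config()) {
  stopifnot(inherits(img, "cbo_micrograph"))
  res <- measure_grey(to_grey(img, depth = config$grey_levels), config)
  res$sample_id <- img$sample_id
  res$technique <- img$technique
  res$replicate_id <- img$replicate_id
  res
}

#' @export
print.cbo_orientation <- function(x, ...) {
  cat(sprintf("<cbo_orientation> index %.3f (major %.1f px, minor %.1f px, angle %.1f deg, threshold %d)\n",
              x$index, x$axes$major_px, x$axes$minor_px,
              x$axes$major_angle_deg, x$threshold_used))
  invisible(x)
}

#' Tidy a measurement into a one-row tibble
#'
#' @param x A `cbo_orientation`.
#' @param ... Unused.
#' @return A tibble with the measurement-record columns.
#' @export
tidy.cbo_orientation <- function(x, ...) {
  tibble(
    sample_id = x$sample_id %||% NA_character_,
    technique = x$technique %||% NA_character_,
    replicate_id = x$replicate_id %||% NA_integer_,
    index = x$index,
    major_px = x$axes$major_px,
    minor_px = x$axes$minor_px,
    major_angle_deg = x$axes$major_angle_deg,
    config_digest = x$config_digest
  )
}

#' Measure a batch of micrographs into a measurement table
#'
#' @param imgs A list of `cbo_micrograph` objects.
#' @param config A [measurement_config()].
#' @return A tibble with one row per image (the measurement-record layout
#'   used by [write_measurements()]).
#' @export
measure_micrographs <- function(imgs, config = measurement_config()) {
  stopifnot(length(imgs) > 0)
  purrr::map_dfr(imgs, function(im) tidy(measure_micrograph(im, config)))
}

#' Average replicate measurements for one sample
#'
#' Each sample is measured on several microphotographs (five in the standard
#' design) and the replicate indices are averaged into the sample-level mean
#' CBO index. A warning is raised when the replicate count differs from 5.
#'
#' @param records A tibble of measurement records for a single sample and
#'   technique (columns `sample_id`, `technique`, `index` at minimum).
#' @param expected_replicates Expected replicate count (default 5).
#' @return A one-row tibble: `sample_id`, `technique`, `n_replicates`,
#'   `mean_index`.
#' @export
average_sample <- function(records, expected_replicates = 5L) {
  stopifnot(is.data.frame(records), nrow(records) >= 1)
  if (length(unique(records$sample_id)) != 1 ||
      length(unique(records$technique)) != 1) {
    abort("records mix multiple samples or techniques.",
          class = "cbo_error_mixed_sample")
  }
  if (nrow(records) != expected_replicates) {
    warn(sprintf("sample %s has %d replicates (expected %d).",
                 records$sample_id[1], nrow(records), expected_replicates))
  }
  tibble(sample_id = records$sample_id[1],
         technique = records$technique[1],
         n_replicates = nrow(records),
         mean_index = mean(records$index))
}

#' Average every sample in a measurement table
#'
#' @param records Measurement tibble (multiple samples/techniques allowed).
#' @inheritParams average_sample
#' @return A tibble with one row per sample x technique.
#' @export
average_samples <- function(records, expected_replicates = 5L) {
  records |>
    dplyr::group_by(.data$sample_id, .data$technique) |>
    dplyr::group_split() |>
    purrr::map_dfr(average_sample, expected_replicates = expected_replicates)
}

measurement_columns <- c("sample_id", "technique", "replicate_id", "index",
                         "major_px", "minor_px", "major_angle_deg",
                         "config_digest")

#' Write measurement records to CSV
#'
#' Comma-separated, UTF-8, `.` decimal; numeric fields are written with
#' enough digits for a lossless roundtrip through [read_measurements()].
#'
#' @param records A non-empty measurement tibble.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_measurements <- function(records, path) {
  if (!is.data.frame(records) || nrow(records) == 0) {
    abort("no records to write.", class = "cbo_error_empty_record_set")
  }
  missing_cols <- setdiff(measurement_columns, names(records))
  if (length(missing_cols) > 0) {
    abort(paste0("records lack column(s): ", paste(missing_cols, collapse = ", ")),
          class = "cbo_error_empty_record_set")
  }
  out <- records[measurement_columns]
  for (col in c("index", "major_px", "minor_px", "major_angle_deg")) {
    out[[col]] <- formatC(out[[col]], digits = 12, format = "g")
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read measurement records from CSV
#'
#' @param path CSV written by [write_measurements()] (or any CSV with the
#'   same header).
#' @return A measurement tibble.
#' @export
read_measurements <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  missing_cols <- setdiff(measurement_columns, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("measurement CSV lacks column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "cbo_error_empty_record_set")
  }
  df$replicate_id <- as.integer(df$replicate_id)
  as_tibble(df[measurement_columns])
}
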