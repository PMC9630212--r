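#' Frozen measurement configuration for synthetic validation studies
#'
#' The synthetic fiber studies use the Hann window (the generator's random
#' fields have periodic-extension discontinuities at the field edges) and a
#' fixed manual threshold of 70 on the gain-100 scale. A fixed manual cut
#' mirrors the semi-automated protocol, in which the operator selects the
#' bright core of the power plot; Otsu's threshold on log-scaled spectra
#' systematically under-segments because the diffuse log floor forms one
#' large class.
#'
#' @return A [measurement_config()].
#' @export
study_config <- function() {
  measurement_config(spectrum_gain = 100, threshold_mode = "manual",
                     manual_threshold = 70L, window = "hann")
}

#' Measurement configuration for band-limited (grating) images
#'
#' Pure gratings concentrate spectral energy in a few small lobes, so the
#' gain is raised to 200 with a manual mid-scale threshold of 128 (the
#' protocol's "adjust the gain until the plot is defined" step), the area
#' filter is relaxed and the blob-scale morphology is reduced so the small
#' lobes survive; the convex hull then merges the conjugate-symmetric lobes
#' into the measured plot.
#'
#' @return A [measurement_config()].
#' @export
grating_config <- function() {
  measurement_config(spectrum_gain = 200, threshold_mode = "manual",
                     manual_threshold = 128L, window = "hann",
                     prefilter_sigma = 0, min_area_fraction = 1e-5,
                     smoothing_radius_px = 1L, spike_removal_radius_px = 0L)
}

#' Generate a pure sinusoidal grating as a grey image
#'
#' @param angle_deg Grating direction in degrees (the direction of the
#'   bands, counterclockwise from the +x/column axis).
#' @param period_px Band period in pixels.
#' @param size_px Square side.
#' @return A [grey_image()] (real-valued, 8-bit range).
#' @export
grating_image <- function(angle_deg = 0, period_px = 12, size_px = 256L) {
  n <- as.integer(size_px)
  a <- angle_deg * pi / 180
  x <- matrix(0:(n - 1), n, n, byrow = TRUE)
  y <- matrix(0:(n - 1), n, n)
  # bands ALONG angle_deg: intensity varies perpendicular to the bands
  phase <- 2 * pi * (-x * sin(a) + y * cos(a)) / period_px + 0.37
  grey_image(127 + 120 * sin(phase), depth = "8bit",
             provenance = list(generator = "grating", angle_deg = angle_deg,
                               period_px = period_px))
}

#' Orientation index of pure gratings across angles
#'
#' @param angles_deg Grating angles to test.
#' @param period_px Band period.
#' @param config Measurement configuration (default [grating_config()]).
#' @return A tibble with `angle_deg` and `index`.
#' @export
grating_study <- function(angles_deg = c(0, 30, 60, 90), period_px = 12,
                          config = grating_config()) {
  purrr::map_dfr(angles_deg, function(a) {
    res <- measure_grey(grating_image(a, period_px), config)
    tibble(angle_deg = a, index = res$index,
           major_angle_deg = res$axes$major_angle_deg)
  })
}

#' Orientation index versus fiber concentration
#'
#' Measures synthetic fiber fields across orientation concentrations and
#' seeds with the pipeline and, optionally, the spectral second-moment
#' anisotropy oracle.
#'
#' @param kappas Concentrations to test.
#' @param n_seeds Fields per concentration.
#' @param seed Base seed; field `i` of concentration `k` uses a distinct
#'   derived seed.
#' @param config Measurement configuration (default [study_config()]).
#' @param oracle Also compute [oracle_spectral_anisotropy()].
#' @return A tibble with `kappa`, `seed`, `index` and optionally `oracle`.
#' @export
kappa_study <- function(kappas = c(0, 1, 2, 4, 8), n_seeds = 20, seed = 1L,
                        config = study_config(), oracle = TRUE) {
  grid <- expand.grid(kappa = kappas, rep = seq_len(n_seeds))
  purrr::map_dfr(seq_len(nrow(grid)), function(i) {
    kap <- grid$kappa[i]
    s <- seed + 1000L * match(kap, kappas) + grid$rep[i]
    g <- generate_fiber_image(fiber_field_params(kappa = kap, seed = s))
    out <- tibble(kappa = kap, seed = s,
                  index = measure_grey(g$image, config)$index)
    if (oracle) out$oracle <- oracle_spectral_anisotropy(g$image)
    out
  })
}

crop_center <- function(m, n) {
  r0 <- (nrow(m) - n) %/% 2
  c0 <- (ncol(m) - n) %/% 2
  m[(r0 + 1):(r0 + n), (c0 + 1):(c0 + n)]
}

#' Rotation robustness of the measurement
#'
#' Generates oversized parallel-fiber fields, measures the central crop, then
#' rotates the field by `angle_deg` (bilinear) and measures the same central
#' crop, reporting the index change and the major-axis angle shift.
#'
#' @param seeds Seeds of the fields.
#' @param kappa Fiber concentration.
#' @param angle_deg Rotation applied to the image.
#' @param config Measurement configuration (default [study_config()]).
#' @return A tibble with `seed`, `index_orig`, `index_rot`, `delta_index`,
#'   `angle_shift_deg` (folded to `[0, 90]`).
#' @export
rotation_study <- function(seeds = 1:3, kappa = 8, angle_deg = 45,
                           config = study_config()) {
  purrr::map_dfr(seeds, function(s) {
    big <- generate_fiber_image(fiber_field_params(size_px = 364L, kappa = kappa,
                                                   seed = s, mean_angle_deg = 20))
    a <- crop_center(big$image$pixels, 256L)
    rot <- EBImage::rotate(big$image$pixels, angle_deg, filter = "bilinear",
                           output.dim = c(364L, 364L), bg.col = 0)
    b <- pmin(pmax(round(crop_center(as.matrix(rot), 256L)), 0), 255)
    ra <- measure_grey(grey_image(a, depth = "8bit"), config)
    rb <- measure_grey(grey_image(b, depth = "8bit"), config)
    shift <- abs(ra$axes$major_angle_deg - rb$axes$major_angle_deg) %% 180
    tibble(seed = s, index_orig = ra$index, index_rot = rb$index,
           delta_index = abs(ra$index - rb$index),
           angle_shift_deg = min(shift, 180 - shift))
  })
}

#' Random filled convex masks for caliper cross-validation
#'
#' Rasterized random ellipses: convex, with a unique caliper-maximum
#' direction, so the "width perpendicular to the maximum length" functional
#' is well conditioned and the two independent measurement routes are
#' comparable at sub-percent level. (Random polygons routinely have two
#' distant vertex pairs at indistinguishable caliper lengths, which makes
#' the perpendicular width ill-posed for any implementation.)
#'
#' @param n_masks Number of masks.
#' @param seed Seed.
#' @param size_px Canvas side.
#' @return A list of logical matrices.
#' @export
random_convex_masks <- function(n_masks = 50, seed = 1L, size_px = 144L) {
  set.seed(seed)
  lapply(seq_len(n_masks), function(i) {
    n <- size_px
    a <- runif(1, 24, n * 0.33)          # semi-major
    b <- a / runif(1, 1.3, 3)            # aspect 1.3-3
    th <- runif(1, 0, pi)
    cx <- runif(1, n * 0.42, n * 0.58)
    cy <- runif(1, n * 0.42, n * 0.58)
    xx <- matrix(seq_len(n), n, n, byrow = TRUE) - cx
    yy <- matrix(seq_len(n), n, n) - cy
    u <- xx * cos(th) + yy * sin(th)
    v <- -xx * sin(th) + yy * cos(th)
    (u / a)^2 + (v / b)^2 <= 1
  })
}

#' Cross-validation of the caliper measurement against the rotation oracle
#'
#' @param n_masks Number of random convex masks.
#' @param seed Seed.
#' @param angle_step_deg Oracle granularity; the default 0.25 degree keeps
#'   the oracle's argmax direction close enough to the exact caliper
#'   direction that the perpendicular widths are comparable.
#' @return A tibble with per-mask major/minor values from both routes and
#'   their relative differences.
#' @export
feret_study <- function(n_masks = 50, seed = 1L, angle_step_deg = 0.25) {
  masks <- random_convex_masks(n_masks, seed)
  purrr::map_dfr(seq_along(masks), function(i) {
    a <- measure_axes(masks[[i]])
    b <- oracle_feret(masks[[i]], angle_step_deg = angle_step_deg)
    tibble(mask = i,
           major = a$major_px, major_oracle = b$major_px,
           minor = a$minor_px, minor_oracle = b$minor_px,
           rel_diff_major = abs(a$major_px - b$major_px) / b$major_px,
           rel_diff_minor = abs(a$minor_px - b$minor_px) / b$minor_px)
  })
}

#' Masson inflation-and-correction study
#'
#' For parallel-fiber Masson scenes with purple cellular blobs: measures the
#' raw scene, the digitally optimized scene (hue segmentation + removal) and
#' the blob-free reference scene built from the same fiber field.
#'
#' @param n_seeds Scenes to simulate.
#' @param seed Base seed.
#' @param kappa Fiber concentration.
#' @param blob_coverage Visible blob coverage target.
#' @param config Measurement configuration (default [study_config()]).
#' @return A tibble with `seed`, `raw`, `optimized`, `clean`, `coverage`,
#'   `jaccard` (segmentation vs. ground truth).
#' @export
masson_study <- function(n_seeds = 20, seed = 1L, kappa = 8,
                         blob_coverage = 0.15, config = study_config()) {
  purrr::map_dfr(seq_len(n_seeds), function(i) {
    s <- seed + i
    sc <- generate_masson_image(masson_scene_params(
      kappa = kappa, seed = s, n_cell_blobs = 200L,
      blob_coverage_target = blob_coverage))
    sc0 <- generate_masson_image(masson_scene_params(
      kappa = kappa, seed = s, n_cell_blobs = 0L, blob_coverage_target = 0))
    seg <- segment_cellular(sc$image)
    opt <- remove_non_collagen(sc$image, seg)
    tibble(seed = s,
           raw = measure_micrograph(sc$image, config)$index,
           optimized = measure_micrograph(opt, config)$index,
           clean = measure_micrograph(sc0$image, config)$index,
           coverage = mean(sc$blob_mask),
           jaccard = sum(seg$mask & sc$blob_mask) /
             sum(seg$mask | sc$blob_mask))
  })
}

#' Simulated interrater study: automatic versus shifted threshold
#'
#' Emulates two raters segmenting the same power plots: rater A uses the
#' automatic Otsu threshold, rater B uses A's threshold shifted by
#' `threshold_delta` grey levels. Samples span the full concentration range;
#' each sample is measured on `n_replicates` fields and per-sample means are
#' compared by the consistency/average-measures ICC.
#'
#' @param n_samples Number of samples (default 21).
#' @param n_replicates Fields per sample (default 5).
#' @param threshold_delta Grey-level shift of rater B (default +10).
#' @param seed Base seed.
#' @param kappas Concentration levels cycled over the samples.
#' @return A list: `means` (n x 2 matrix of per-sample means), `icc`
#'   (a `cbo_icc`), `records` (per-field tibble).
#' @export
interrater_study <- function(n_samples = 21, n_replicates = 5,
                             threshold_delta = 10L, seed = 1L,
                             kappas = c(0, 1, 2, 4, 8)) {
  kap <- rep(kappas, length.out = n_samples)
  cfg_a <- measurement_config(window = "hann")  # auto Otsu
  rows <- list()
  for (i in seq_len(n_samples)) {
    for (r in seq_len(n_replicates)) {
      s <- seed + i * 100L + r
      g <- generate_fiber_image(fiber_field_params(kappa = kap[i], seed = s))
      ra <- measure_grey(g$image, cfg_a)
      thr_b <- as.integer(min(255, max(0, ra$threshold_used + threshold_delta)))
      cfg_b <- measurement_config(window = "hann", threshold_mode = "manual",
                                  manual_threshold = thr_b)
      rb <- measure_grey(g$image, cfg_b)
      rows[[length(rows) + 1L]] <- tibble(
        sample = i, replicate = r, kappa = kap[i],
        rater_a = ra$index, rater_b = rb$index,
        threshold_a = ra$threshold_used, threshold_b = thr_b)
    }
  }
  records <- dplyr::bind_rows(rows)
  means <- records |>
    dplyr::group_by(.data$sample) |>
    dplyr::summarise(rater_a = mean(.data$rater_a),
                     rater_b = mean(.data$rater_b), .groups = "drop")
  m <- as.matrix(means[c("rater_a", "rater_b")])
  list(means = m, icc = icc_consistency_average(m), records = records)
}
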