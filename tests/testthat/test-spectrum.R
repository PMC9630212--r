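test_that("a grating's spectrum concentrates at the carrier frequency, symmetrically", {
  n <- 128
  g <- grating_image(angle_deg = 0, period_px = 16, size_px = n)
  ps <- compute_power_spectrum(g, gain = 100, window = "none")
  v <- ps$values
  dc <- ps$dc
  # two brightest off-DC bins sit at row offsets +-n/16 on the DC column
  v[dc[1], dc[2]] <- 0
  ord <- order(v, decreasing = TRUE)[1:2]
  rows <- (ord - 1) %% n + 1
  cols <- (ord - 1) %/% n + 1
  expect_setequal(rows, c(dc[1] - 8, dc[1] + 8))
  expect_equal(cols, c(dc[2], dc[2]))

  # point symmetry about DC (away from the unmatched Nyquist row/column)
  set.seed(5)
  r <- compute_power_spectrum(random_grey(64), gain = 100, window = "none")
  vv <- r$values[-1, -1]
  flipped <- vv[rev(seq_len(nrow(vv))), rev(seq_len(ncol(vv)))]
  expect_equal(vv, flipped, tolerance = 1e-6)
})

test_that("gain rescales the spectrum pointwise below the clip", {
  g <- random_grey(96, seed = 11)
  v70 <- compute_power_spectrum(g, gain = 70, window = "none")$values
  v200 <- compute_power_spectrum(g, gain = 200, window = "none")$values
  keep <- v200 < 255
  expect_equal(v200[keep], (200 / 70) * v70[keep], tolerance = 1e-9)
  expect_true(all(v200 <= 255))
})

test_that("degenerate and undersized images are rejected", {
  expect_error(compute_power_spectrum(grey_image(matrix(3, 64, 64), "8bit")),
               class = "cbo_error_degenerate_image")
  expect_error(
    compute_power_spectrum(grey_image(matrix(runif(32 * 32), 32, 32), "8bit")),
    class = "cbo_error_image_too_small")
})

test_that("automatic threshold matches a brute-force Otsu oracle", {
  for (seed in 1:5) {
    ps <- compute_power_spectrum(random_grey(96, seed = seed), gain = 100,
                                 window = "hann", prefilter_sigma = 1.5)
    sm <- segment_spectrum(ps, mode = "auto")
    expect_identical(sm$threshold_used, otsu_oracle(ps$values))
  }
})

test_that("manual segmentation respects the 0-255 scale contract", {
  ps <- compute_power_spectrum(random_grey(96, seed = 2), gain = 100)
  full <- segment_spectrum(ps, mode = "manual", manual_threshold = 0L)
  expect_true(all(full$mask))
  # full square mask has equal caliper extents: index 1 within discretization
  ax <- measure_axes(full)
  expect_equal(orientation_index(ax), 1, tolerance = 0.01)
  expect_error(segment_spectrum(ps, mode = "manual", manual_threshold = 255L),
               class = "cbo_error_empty_mask")
  expect_error(segment_spectrum(ps, mode = "manual"),
               class = "cbo_error_invalid_config")
})

test_that("mask cleanup removes specks, fills holes and can take the hull", {
  n <- 128
  dc <- c(n %/% 2 + 1L, n %/% 2 + 1L)
  blob <- matrix(FALSE, n, n)
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  blob[(rr - dc[1])^2 + (cc - dc[2])^2 <= 20^2] <- TRUE
  ring <- blob & !((rr - dc[1])^2 + (cc - dc[2])^2 <= 8^2)  # interior hole
  speck <- ring
  speck[5:6, 5:6] <- TRUE  # 4-px satellite, below the area filter

  sm <- structure(list(mask = speck, threshold_used = 50L,
                       area_px = sum(speck), dc = dc), class = "cbo_mask")
  cleaned <- clean_mask(sm, min_area_fraction = 5e-4, smoothing_radius_px = 0L,
                        apply_convex_hull = FALSE)
  expect_false(any(cleaned$mask[1:10, 1:10]))      # speck removed
  expect_gt(cleaned$area_px, sum(ring) - 4)        # hole filled
  expect_true(all(cleaned$mask[blob]))

  cross <- matrix(FALSE, n, n)
  cross[(dc[1] - 30):(dc[1] + 30), (dc[2] - 4):(dc[2] + 4)] <- TRUE
  cross[(dc[1] - 4):(dc[1] + 4), (dc[2] - 30):(dc[2] + 30)] <- TRUE
  smc <- structure(list(mask = cross, threshold_used = 50L,
                        area_px = sum(cross), dc = dc), class = "cbo_mask")
  hulled <- clean_mask(smc, smoothing_radius_px = 0L, apply_convex_hull = TRUE)
  expect_true(all(hulled$mask[cross]))             # hull is a superset
  expect_gt(hulled$area_px, sum(cross))
})

test_that("spike removal strips thin radial structures but not the blob", {
  n <- 192
  dc <- c(n %/% 2 + 1L, n %/% 2 + 1L)
  rr <- matrix(seq_len(n), n, n)
  cc <- t(rr)
  disk <- (rr - dc[1])^2 + (cc - dc[2])^2 <= 40^2
  spiked <- disk
  spiked[dc[1] + (-1:1), dc[2]:(dc[2] + 95)] <- TRUE  # 3-px-wide, ~100-px spike
  sm <- structure(list(mask = spiked, threshold_used = 50L,
                       area_px = sum(spiked), dc = dc), class = "cbo_mask")

  before <- oracle_feret(sm, angle_step_deg = 1)
  expect_gt(before$major_px, 130)
  after <- split_spikes(sm, spike_removal_radius_px = 3L)
  ax <- oracle_feret(after, angle_step_deg = 1)
  expect_lt(ax$major_px, 85)
  expect_gt(ax$major_px, 75)

  # radius 0 is the identity
  expect_identical(split_spikes(sm, 0L)$mask, sm$mask)

  # a mask thinner than the disk everywhere falls back with a warning
  thin <- matrix(FALSE, n, n)
  thin[dc[1], (dc[2] - 30):(dc[2] + 30)] <- TRUE
  smt <- structure(list(mask = thin, threshold_used = 50L,
                        area_px = sum(thin), dc = dc), class = "cbo_mask")
  expect_warning(out <- split_spikes(smt, 3L), "empty")
  expect_identical(out$mask, thin)
})

test_that("the full measurement is deterministic", {
  g <- generate_fiber_image(fiber_field_params(kappa = 4, seed = 9))
  cfg <- study_config()
  r1 <- measure_grey(g$image, cfg)
  r2 <- measure_grey(g$image, cfg)
  expect_identical(r1$index, r2$index)
  expect_identical(r1$axes, r2$axes)
  expect_identical(r1$threshold_used, r2$threshold_used)
  expect_gt(r1$index, 0)
  expect_lte(r1$index, 1)
})
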