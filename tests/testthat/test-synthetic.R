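test_that("generators are pure functions of their seed", {
  p <- fiber_field_params(kappa = 2, seed = 123)
  a <- generate_fiber_image(p)
  b <- generate_fiber_image(p)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$angles, b$angles)

  mp <- masson_scene_params(kappa = 2, seed = 123)
  ma <- generate_masson_image(mp)
  mb <- generate_masson_image(mp)
  expect_identical(ma$image$pixels, mb$image$pixels)
  expect_identical(ma$blob_mask, mb$blob_mask)
})

test_that("fiber angles follow the axial von Mises law", {
  # concentration limit: all angles within 1 degree of the mean direction
  g <- generate_fiber_image(fiber_field_params(kappa = 1e6, seed = 2,
                                               mean_angle_deg = 40,
                                               n_fibers = 300L))
  d <- abs(((g$angles * 180 / pi - 40 + 90) %% 180) - 90)
  expect_lt(max(d), 1)

  # kappa = 0: axial-uniform, doubled-angle resultant near zero
  u <- generate_fiber_image(fiber_field_params(kappa = 0, seed = 3,
                                               n_fibers = 500L))
  resultant <- Mod(mean(exp(2i * u$angles)))
  expect_lt(resultant, 0.15)

  # moderate concentration: angular spread matches 1/(2 sqrt(kappa))
  m <- generate_fiber_image(fiber_field_params(kappa = 8, seed = 4,
                                               n_fibers = 512L,
                                               mean_angle_deg = 30))
  dev <- ((m$angles * 180 / pi - 30 + 90) %% 180) - 90
  expect_equal(sd(dev), 1 / (2 * sqrt(8)) * 180 / pi, tolerance = 0.15)

  expect_error(fiber_field_params(size_px = 128), class = "cbo_error_invalid_params")
  expect_error(fiber_field_params(fiber_length_px = c(5, 2)),
               class = "cbo_error_invalid_params")
})

test_that("Masson scenes hit the blob coverage target with separable hues", {
  sc <- generate_masson_image(masson_scene_params(kappa = 8, seed = 5,
                                                  n_cell_blobs = 200L,
                                                  blob_coverage_target = 0.15))
  expect_gte(mean(sc$blob_mask), 0.10)
  expect_lte(mean(sc$blob_mask), 0.20)

  seg <- segment_cellular(sc$image)
  jac <- sum(seg$mask & sc$blob_mask) / sum(seg$mask | sc$blob_mask)
  expect_gte(jac, 0.9)

  none <- generate_masson_image(masson_scene_params(kappa = 8, seed = 5,
                                                    n_cell_blobs = 0L,
                                                    blob_coverage_target = 0))
  expect_equal(segment_cellular(none$image)$coverage_fraction, 0)

  expect_error(
    masson_scene_params(collagen_color = c(170, 60, 170)),  # same hue as blobs
    class = "cbo_error_invalid_params")
})

test_that("spectral second-moment oracle separates noise from gratings", {
  vals <- vapply(1:5, function(s) {
    oracle_spectral_anisotropy(random_grey(128, seed = s))
  }, numeric(1))
  expect_gte(mean(vals), 0.9)

  g <- grating_image(angle_deg = 30, period_px = 16, size_px = 128)
  expect_lte(oracle_spectral_anisotropy(g), 0.1)

  # rotation by 90 degrees is an exact frequency-grid transposition (odd
  # side, so every frequency bin has its rotated partner on the grid)
  m <- random_grey(127, seed = 9)$pixels
  rot90 <- t(m)[, rev(seq_len(ncol(m)))]
  expect_equal(oracle_spectral_anisotropy(grey_image(m, "8bit")),
               oracle_spectral_anisotropy(grey_image(rot90, "8bit")),
               tolerance = 1e-6)
})

test_that("fiber images after non-collagen removal measure no more random than raw", {
  res <- masson_study(n_seeds = 2, seed = 50)
  expect_true(all(res$jaccard >= 0.9))
  expect_gte(mean(res$raw), mean(res$optimized))
})
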