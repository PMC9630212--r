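test_that("best-fit contrast stretches to the full range and is idempotent", {
  vals <- matrix(rep(10:50, length.out = 64 * 64), 64, 64)
  g <- grey_image(vals, depth = "8bit")
  out <- best_fit_contrast(g, clip_percentile = 0)
  expect_equal(min(out$pixels), 0)
  expect_equal(max(out$pixels), 255)
  expect_equal(out$pixels, (vals - 10) / 40 * 255, tolerance = 1e-12)

  # already full-range image is a fixed point at clip 0
  full <- grey_image(matrix(rep(c(0, 255), length.out = 64 * 64), 64, 64),
                     depth = "8bit")
  once <- best_fit_contrast(full, 0)
  expect_equal(once$pixels, full$pixels)
  twice <- best_fit_contrast(best_fit_contrast(g, 0), 0)
  expect_equal(twice$pixels, out$pixels)

  const <- grey_image(matrix(7, 64, 64), depth = "8bit")
  expect_error(best_fit_contrast(const, 0), class = "cbo_error_degenerate_image")
})

test_that("greyscale conversion follows the Rec.601 luminance weights", {
  arr <- array(0, c(64, 64, 3))
  arr[, , 1] <- 255
  arr[, , 2] <- 255
  arr[, , 3] <- 255
  white <- micrograph(arr)
  expect_equal(max(to_grey(white, "16bit")$pixels), 65535)
  expect_equal(min(to_grey(white, "16bit")$pixels), 65535)

  arr[] <- 0
  arr[, , 2] <- 255
  green <- micrograph(arr)
  expect_equal(to_grey(green, "8bit")$pixels[1, 1], 0.587 * 255, tolerance = 1e-9)

  set.seed(3)
  m <- matrix(round(runif(64 * 64, 0, 255)), 64, 64)
  rep3 <- micrograph(array(rep(m, 3), c(64, 64, 3)))
  expect_equal(to_grey(rep3, "8bit")$pixels, m, tolerance = 1e-9)
})

test_that("purple segmentation selects exactly the known blob", {
  px <- toy_masson_array(96, blob = TRUE, blob_frac = 0.1)
  img <- micrograph(px, technique = "masson")
  seg <- segment_cellular(img)
  blob <- attr(px, "blob")
  truth <- matrix(FALSE, 96, 96)
  truth[blob$rows, blob$cols] <- TRUE
  expect_identical(seg$mask, truth)
  expect_equal(seg$coverage_fraction, mean(truth))
  expect_equal(seg$coverage_fraction, 0.1, tolerance = 0.05)

  none <- micrograph(toy_masson_array(96, blob = FALSE), technique = "masson")
  seg0 <- segment_cellular(none)
  expect_false(any(seg0$mask))
  expect_equal(seg0$coverage_fraction, 0)

  expect_error(segment_cellular(img, hue_range_deg = c(400, 20)),
               class = "cbo_error_invalid_hue_range")
  pic <- micrograph(px, technique = "picrosirius")
  expect_error(segment_cellular(pic), class = "cbo_error_invalid_config")
})

test_that("non-collagen removal touches only masked pixels and removes purple", {
  px <- toy_masson_array(96, blob = TRUE)
  img <- micrograph(px, technique = "masson")
  seg <- segment_cellular(img)

  # all-false mask: identity except the technique label
  none <- structure(list(mask = matrix(FALSE, 96, 96)), class = "cbo_cellular_mask")
  out0 <- remove_non_collagen(img, none)
  expect_identical(out0$pixels, img$pixels)
  expect_identical(out0$technique, "masson_optimized")

  # unmasked pixels are bit-identical regardless of fill mode
  for (fm in c("local_background", "background_mean", "white")) {
    out <- remove_non_collagen(img, seg, fill_mode = fm)
    keep <- !seg$mask
    for (ch in 1:3) {
      expect_identical(out$pixels[, , ch][keep], img$pixels[, , ch][keep])
    }
  }

  # white fill with no feather leaves no pixel in the purple hue band
  outw <- remove_non_collagen(img, seg, fill_mode = "white", feather_sigma_px = 0)
  seg2 <- segment_cellular(micrograph(outw$pixels, technique = "masson"))
  expect_false(any(seg2$mask))

  big <- structure(list(mask = matrix(TRUE, 96, 96)), class = "cbo_cellular_mask")
  big$mask[1:10, 1:10] <- FALSE  # 96% coverage
  expect_error(remove_non_collagen(img, big), class = "cbo_error_mask_too_large")
  expect_error(remove_non_collagen(img, matrix(FALSE, 10, 10)),
               class = "cbo_error_mask_mismatch")
})
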