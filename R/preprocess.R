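#' Best-fit contrast stretch
#'
#' Linear rescale mapping the `clip_percentile`-th percentile of the grey
#' values to the range minimum and the `(100 - clip_percentile)`-th to the
#' range maximum, clipping outside. With `clip_percentile = 0` this is the
#' classic min-max stretch and is idempotent.
#'
#' @param grey A [grey_image()].
#' @param clip_percentile Percentile clipped at each end, in `[0, 5)`.
#' @return A `cbo_grey` spanning the full declared range.
#' @export
best_fit_contrast <- function(grey, clip_percentile = 0.5) {
  stopifnot(inherits(grey, "cbo_grey"))
  if (clip_percentile < 0 || clip_percentile >= 5) {
    abort("`clip_percentile` must lie in [0, 5).", class = "cbo_error_invalid_config")
  }
  px <- grey$pixels
  lo <- quantile(px, clip_percentile / 100, names = FALSE, type = 7)
  hi <- quantile(px, 1 - clip_percentile / 100, names = FALSE, type = 7)
  if (hi <= lo) {
    abort("image is constant (or constant after clipping); contrast undefined.",
          class = "cbo_error_degenerate_image")
  }
  dmax <- depth_max(grey$depth)
  out <- (px - lo) / (hi - lo) * dmax
  out[out < 0] <- 0
  out[out > dmax] <- dmax
  grey_image(out, depth = grey$depth, provenance = grey$provenance)
}

#' Segment purple-stained cellular structures
#'
#' Classifies pixels by hue/saturation/value. A pixel belongs to the cellular
#' mask iff its hue lies in the (circular) `hue_range_deg` interval, its
#' saturation is at least `min_saturation` and its value at least
#' `min_value`. The defaults cover the magenta-purple band of Masson-stained
#' cellular components, well separated from the blue collagen hue.
#'
#' @param img A `cbo_micrograph` with technique `"masson"` or `"synthetic"`.
#' @param hue_range_deg Length-2 vector of hue bounds in degrees `[0, 360)`;
#'   an interval with `lo > hi` wraps through 0.
#' @param min_saturation,min_value HSV thresholds in `[0, 1]`.
#' @return A `cbo_cellular_mask`: list with `mask` (H x W logical),
#'   `hue_range_deg` and `coverage_fraction`.
#' @export
segment_cellular <- function(img, hue_range_deg = c(260, 340),
                             min_saturation = 0.15, min_value = 0.10) {
  stopifnot(inherits(img, "cbo_micrograph"))
  if (!img$technique %in% c("masson", "synthetic")) {
    abort("cellular segmentation is defined for Masson or synthetic images.",
          class = "cbo_error_invalid_config")
  }
  if (length(hue_range_deg) != 2 || anyNA(hue_range_deg) ||
      any(hue_range_deg < 0) || any(hue_range_deg >= 360)) {
    abort("`hue_range_deg` must be two values in [0, 360).",
          class = "cbo_error_invalid_hue_range")
  }
  d <- dim(img$pixels)
  rgb <- matrix(aperm(img$pixels, c(3, 1, 2)), nrow = 3)
  hsv <- grDevices::rgb2hsv(rgb, maxColorValue = 255)
  hue <- hsv[1, ] * 360
  in_hue <- if (hue_range_deg[1] <= hue_range_deg[2]) {
    hue >= hue_range_deg[1] & hue <= hue_range_deg[2]
  } else {
    hue >= hue_range_deg[1] | hue <= hue_range_deg[2]
  }
  sel <- in_hue & hsv[2, ] >= min_saturation & hsv[3, ] >= min_value
  mask <- matrix(sel, d[1], d[2])
  structure(list(mask = mask, hue_range_deg = hue_range_deg,
                 coverage_fraction = mean(mask)),
            class = "cbo_cellular_mask")
}

#' Remove non-collagen structures from a Masson micrograph
#'
#' Replaces the pixels under a cellular mask with either the mean color of
#' the unmasked (background + collagen) pixels or pure white, producing the
#' digitally "optimized" Masson image in which only collagenous components
#' contribute to the orientation measurement. Unmasked pixels are untouched.
#'
#' @param img A `cbo_micrograph`.
#' @param mask A [segment_cellular()] result (or compatible list) whose mask
#'   matches the image dimensions and covers less than 95% of the field.
#' @param fill_mode `"local_background"` (default: normalized-convolution
#'   inpainting restricted to the bright background class - each removed
#'   pixel takes the Gaussian-weighted mean color of the surrounding
#'   unmasked background pixels, since the removed cellular structures sit in
#'   interstitial background space), `"background_mean"` (global mean of the
#'   unmasked pixels) or `"white"`.
#' @param dilation_px Disk radius by which the mask is dilated before
#'   removal, to catch the partially-stained halo around cellular
#'   structures; 0 disables.
#' @param fill_sigma_px Gaussian scale of the `local_mean` fill, in pixels;
#'   should be of the order of the removed structures' radius.
#' @param feather_sigma_px After filling, the masked pixels are re-estimated
#'   from a Gaussian blur of the filled image at this scale, so the fill
#'   boundary is as soft as the optically blurred structures around it
#'   (unfiltered hard fill edges would inject broadband power into the
#'   spectrum). Unmasked pixels remain bit-identical. 0 disables.
#' @return A `cbo_micrograph` with technique `"masson_optimized"`.
#' @export
remove_non_collagen <- function(img, mask,
                                fill_mode = c("local_background",
                                              "background_mean", "white"),
                                dilation_px = 0L, fill_sigma_px = 12,
                                feather_sigma_px = 1.2) {
  fill_mode <- match.arg(fill_mode)
  stopifnot(inherits(img, "cbo_micrograph"))
  m <- if (inherits(mask, "cbo_cellular_mask")) mask$mask else mask
  if (dilation_px > 0 && any(m)) {
    k <- EBImage::makeBrush(2L * as.integer(dilation_px) + 1L, "disc")
    m <- as.matrix(EBImage::dilate(m, k)) > 0
  }
  d <- dim(img$pixels)
  if (!is.matrix(m) || !all(dim(m) == d[1:2])) {
    abort("mask dimensions do not match the image.", class = "cbo_error_mask_mismatch")
  }
  cov <- mean(m)
  if (cov >= 0.95) {
    abort(sprintf("mask covers %.1f%% of the field; refusing to remove >= 95%%.",
                  100 * cov),
          class = "cbo_error_mask_too_large")
  }
  px <- img$pixels
  if (fill_mode == "local_background" && any(m) && any(!m)) {
    lum <- 0.299 * px[, , 1] + 0.587 * px[, , 2] + 0.114 * px[, , 3]
    # bright (background) class among unmasked pixels, via Otsu on luminance
    thr <- otsu_threshold(matrix(pmax(lum[!m], 1e-3)))
    ref <- !m & lum >= thr
    if (!any(ref)) ref <- !m
    w <- matrix(as.numeric(ref), nrow(m), ncol(m))
    wb <- as.matrix(EBImage::gblur(w, sigma = fill_sigma_px))
    wb[wb < 1e-6] <- 1e-6
    for (ch in 1:3) {
      plane <- px[, , ch]
      masked0 <- plane
      masked0[!ref] <- 0
      fillv <- as.matrix(EBImage::gblur(masked0, sigma = fill_sigma_px)) / wb
      plane[m] <- pmin(pmax(fillv[m], 0), 255)
      px[, , ch] <- plane
    }
  } else {
    fill <- if (fill_mode == "background_mean" && any(!m)) {
      c(mean(px[, , 1][!m]), mean(px[, , 2][!m]), mean(px[, , 3][!m]))
    } else {
      c(255, 255, 255)
    }
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[m] <- fill[ch]
      px[, , ch] <- plane
    }
  }
  if (feather_sigma_px > 0 && any(m)) {
    for (ch in 1:3) {
      plane <- px[, , ch]
      soft <- as.matrix(EBImage::gblur(plane, sigma = feather_sigma_px))
      plane[m] <- pmin(pmax(soft[m], 0), 255)
      px[, , ch] <- plane
    }
  }
  out <- img
  out$pixels <- px
  out$technique <- "masson_optimized"
  out
}
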