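#' Compute the log-scaled 2D power plot of a grey image
#'
#' The image is center-cropped to the largest centered square, mean-subtracted,
#' optionally apodized with a 2D Hann window, Fourier-transformed with the DC
#' bin shifted to the array center, log-compressed (`log(1 + |F|)`) and scaled
#' by `gain / max` onto the 0-255 display range (clipped above 255). The DC
#' bin, artificially zeroed by the mean subtraction, is set to the maximum of
#' its 8 neighbors before scaling.
#'
#' @param grey A [grey_image()]; both dimensions must be at least 64 and the
#'   image must not be constant.
#' @param gain Spectrum gain (see [measurement_config()]).
#' @param window `"none"` or `"hann"`.
#' @param prefilter_sigma Gaussian smoothing (frequency bins) applied to the
#'   scaled plot; 0 disables.
#' @return A `cbo_spectrum`: list with `values` (square matrix in `[0, 255]`),
#'   `gain`, `window`, `dc` (row, col of the DC bin).
#' @export
compute_power_spectrum <- function(grey, gain = 100, window = c("none", "hann"),
                                   prefilter_sigma = 0) {
  window <- match.arg(window)
  stopifnot(inherits(grey, "cbo_grey"))
  px <- grey$pixels
  if (min(dim(px)) < 64) {
    abort("image smaller than 64 px per side.", class = "cbo_error_image_too_small")
  }
  n <- min(dim(px))
  r0 <- (nrow(px) - n) %/% 2
  c0 <- (ncol(px) - n) %/% 2
  px <- px[(r0 + 1):(r0 + n), (c0 + 1):(c0 + n)]
  if (max(px) == min(px)) {
    abort("constant image has no defined power plot.",
          class = "cbo_error_degenerate_image")
  }
  x <- px - mean(px)
  if (window == "hann") {
    w <- 0.5 * (1 - cos(2 * pi * (0:(n - 1)) / (n - 1)))
    x <- x * outer(w, w)
  }
  s <- log1p(Mod(fftshift(fft(x))))
  dc <- c(n %/% 2 + 1L, n %/% 2 + 1L)
  nb <- s[dc[1] + (-1:1), dc[2] + (-1:1)]
  nb[2, 2] <- NA
  s[dc[1], dc[2]] <- max(nb, na.rm = TRUE)
  smax <- max(s)
  if (smax <= 0) {
    abort("degenerate spectrum.", class = "cbo_error_degenerate_image")
  }
  v <- gain * s / smax
  v[v > 255] <- 255
  if (prefilter_sigma > 0) {
    v <- as.matrix(EBImage::gblur(v, sigma = prefilter_sigma))
    v[v < 0] <- 0
    v[v > 255] <- 255
  }
  structure(list(values = v, gain = gain, window = window, dc = dc),
            class = "cbo_spectrum")
}

# moves the DC bin (index 1) to index n %/% 2 + 1, for even or odd n
fftshift <- function(m) {
  n <- nrow(m)
  s <- as.integer(ceiling(n / 2))
  m[c((s + 1):n, 1:s), c((s + 1):n, 1:s)]
}

#' @export
print.cbo_spectrum <- function(x, ...) {
  cat(sprintf("<cbo_spectrum> %d x %d, gain %g, window %s\n",
              nrow(x$values), ncol(x$values), x$gain, x$window))
  invisible(x)
}

#' Otsu threshold of the spectrum values
#'
#' Brute-force maximization of the between-class variance over the 256 grey
#' levels of the rounded non-zero spectrum values.
#'
#' @param values Numeric matrix in `[0, 255]`.
#' @return Integer threshold in 0-255.
#' @export
otsu_threshold <- function(values) {
  x <- round(values[values > 0])
  if (length(x) == 0) return(0L)
  h <- tabulate(as.integer(x) + 1L, 256L)
  p <- h / sum(h)
  om <- cumsum(p)
  mu <- cumsum(p * (0:255))
  mu_t <- mu[256]
  sb <- (mu_t * om - mu)^2 / (om * (1 - om))
  sb[!is.finite(sb)] <- 0
  # threshold t keeps classes [0, t] and (t, 255]; mask rule is >= t + 1
  as.integer(which.max(sb))
}

# 8-connected labeling: EBImage::bwlabel (4-connected) + merging of
# diagonally adjacent labels through an igraph components pass.
label_components <- function(mask) {
  lab <- EBImage::bwlabel(mask)
  nl <- max(lab)
  if (nl <= 1) return(lab)
  a <- lab[-nrow(lab), -ncol(lab)]
  b <- lab[-1, -1]
  c1 <- lab[-nrow(lab), -1]
  d1 <- lab[-1, -ncol(lab)]
  pairs <- rbind(cbind(as.vector(a), as.vector(b)),
                 cbind(as.vector(c1), as.vector(d1)))
  pairs <- pairs[pairs[, 1] > 0 & pairs[, 2] > 0 & pairs[, 1] != pairs[, 2], ,
                 drop = FALSE]
  if (nrow(pairs) == 0) return(lab)
  g <- igraph::graph_from_edgelist(unique(pairs), directed = FALSE)
  g <- igraph::add_vertices(g, max(0, nl - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  out <- lab
  out[lab > 0] <- memb[lab[lab > 0]]
  out
}

# Filled convex hull of a logical mask (chull vertices + point-in-polygon).
convex_hull_mask <- function(mask) {
  idx <- which(mask, arr.ind = TRUE)
  if (nrow(idx) < 3) return(mask)
  h <- grDevices::chull(idx[, 1], idx[, 2])
  hp <- idx[h, , drop = FALSE]
  rr <- range(idx[, 1])
  cc <- range(idx[, 2])
  gr <- expand.grid(r = rr[1]:rr[2], c = cc[1]:cc[2])
  inp <- pracma::inpolygon(gr$r, gr$c, hp[, 1], hp[, 2], boundary = TRUE)
  out <- mask
  out[, ] <- FALSE
  out[cbind(gr$r[inp], gr$c[inp])] <- TRUE
  out | mask
}

# keep components passing the area filter; the DC-containing component is
# always retained when present; fall back to the largest component.
filter_components <- function(mask, dc, min_area) {
  lab <- label_components(mask)
  if (max(lab) == 0) return(mask)
  areas <- tabulate(lab[lab > 0])
  keep <- which(areas >= min_area)
  dl <- lab[dc[1], dc[2]]
  if (dl > 0) keep <- union(keep, dl)
  if (length(keep) == 0) keep <- which.max(areas)
  matrix(lab %in% keep, nrow(mask), ncol(mask))
}

#' Segment the central frequencies of a power plot
#'
#' Thresholds the 0-255 power plot, either automatically (Otsu's method on
#' the non-zero values) or at a fixed manual level, mirroring the protocol's
#' manual segmentation step.
#'
#' @param ps A [compute_power_spectrum()] result.
#' @param mode `"auto"` or `"manual"`.
#' @param manual_threshold Integer 0-255, used when `mode = "manual"`.
#' @return A `cbo_mask`: list with `mask` (logical matrix), `threshold_used`,
#'   `area_px` and `dc`.
#' @export
segment_spectrum <- function(ps, mode = c("auto", "manual"),
                             manual_threshold = NA_integer_) {
  mode <- match.arg(mode)
  stopifnot(inherits(ps, "cbo_spectrum"))
  thr <- if (mode == "auto") {
    otsu_threshold(ps$values)
  } else {
    if (is.na(manual_threshold)) {
      abort("`manual_threshold` required in manual mode.",
            class = "cbo_error_invalid_config")
    }
    as.integer(manual_threshold)
  }
  mask <- ps$values >= thr
  if (!any(mask)) {
    abort(sprintf("threshold %d excludes the entire power plot.", thr),
          class = "cbo_error_empty_mask")
  }
  spectrum_mask(mask, threshold_used = thr, dc = ps$dc)
}

spectrum_mask <- function(mask, threshold_used, dc) {
  structure(list(mask = mask, threshold_used = as.integer(threshold_used),
                 area_px = sum(mask), dc = dc),
            class = "cbo_mask")
}

#' @export
print.cbo_mask <- function(x, ...) {
  cat(sprintf("<cbo_mask> %d x %d, %d px, threshold %d\n",
              nrow(x$mask), ncol(x$mask), x$area_px, x$threshold_used))
  invisible(x)
}

#' Clean a segmented power plot
#'
#' In order: (1) drop connected components smaller than
#' `min_area_fraction * area` (the DC-containing component is always kept);
#' (2) fill holes; (3) morphological closing then opening with a disk of
#' `smoothing_radius_px`; (4) re-apply the component filter; (5) optionally
#' replace the surviving set by its filled convex hull, which also merges the
#' conjugate-symmetric lobes of band-limited spectra into the single plot
#' that is measured.
#'
#' @param sm A [segment_spectrum()] result.
#' @param min_area_fraction,smoothing_radius_px,apply_convex_hull See
#'   [measurement_config()].
#' @return A cleaned `cbo_mask`.
#' @export
clean_mask <- function(sm, min_area_fraction = 5e-4, smoothing_radius_px = 2L,
                       apply_convex_hull = TRUE) {
  stopifnot(inherits(sm, "cbo_mask"))
  mask <- sm$mask
  if (!any(mask)) {
    abort("mask is empty.", class = "cbo_error_empty_mask")
  }
  n2 <- length(mask)
  min_area <- max(3, min_area_fraction * n2)
  mask <- filter_components(mask, sm$dc, min_area)
  mask <- as.matrix(EBImage::fillHull(mask)) > 0
  if (smoothing_radius_px > 0) {
    k <- EBImage::makeBrush(2L * as.integer(smoothing_radius_px) + 1L, "disc")
    sm2 <- as.matrix(EBImage::opening(EBImage::closing(mask, k), k)) > 0
    if (sum(sm2) >= 3) mask <- sm2
    mask <- filter_components(mask, sm$dc, min_area)
  }
  if (apply_convex_hull) {
    mask <- convex_hull_mask(mask)
  }
  if (!any(mask)) {
    abort("cleanup removed the entire mask.", class = "cbo_error_empty_mask")
  }
  spectrum_mask(mask, threshold_used = sm$threshold_used, dc = sm$dc)
}

#' Remove thin spikes from a segmented power plot
#'
#' Automated surrogate for manual spike exclusion: a morphological opening
#' with a disk of `spike_removal_radius_px` removes radial structures thinner
#' than the disk (such as the axis-aligned leakage cross from image edges).
#' If the opening would empty the mask, the input is returned unchanged with
#' a warning. Radius 0 is a no-op.
#'
#' @param sm A `cbo_mask`.
#' @param spike_removal_radius_px Disk radius in pixels.
#' @param min_area_fraction Component filter re-applied after the opening.
#' @return A `cbo_mask`.
#' @export
split_spikes <- function(sm, spike_removal_radius_px = 3L,
                         min_area_fraction = 5e-4) {
  stopifnot(inherits(sm, "cbo_mask"))
  r <- as.integer(spike_removal_radius_px)
  if (r <= 0) return(sm)
  k <- EBImage::makeBrush(2L * r + 1L, "disc")
  opened <- as.matrix(EBImage::opening(sm$mask, k)) > 0
  if (sum(opened) < 3) {
    warn("spike-removal opening would empty the mask; keeping the input mask.")
    return(sm)
  }
  opened <- filter_components(opened, sm$dc,
                              max(3, min_area_fraction * length(opened)))
  spectrum_mask(opened, threshold_used = sm$threshold_used, dc = sm$dc)
}
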