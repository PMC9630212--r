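#' Sample von Mises angles (Best-Fisher rejection sampler)
#'
#' @param n Number of draws.
#' @param mu Mean direction in radians.
#' @param kappa Concentration, `>= 0`; 0 gives the circular uniform.
#' @return Angles in `[0, 2 pi)`.
#' @keywords internal
rvonmises <- function(n, mu, kappa) {
  if (kappa < 1e-8) return(runif(n, 0, 2 * pi))
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  i <- 1L
  while (i <= n) {
    u <- runif(3)
    z <- cos(pi * u[1])
    f <- (1 + r * z) / (r + z)
    cc <- kappa * (r - f)
    if (cc * (2 - cc) - u[2] > 0 || log(cc / u[2]) + 1 - cc >= 0) {
      out[i] <- (mu + sign(u[3] - 0.5) * acos(f)) %% (2 * pi)
      i <- i + 1L
    }
  }
  out
}

#' Parameters of a synthetic fiber field
#'
#' Defines the texture model used throughout validation: straight,
#' anti-aliased fiber segments whose orientations follow an axial von Mises
#' law (angles doubled onto the circle, concentration `kappa`), with
#' stratified random centers (suppressing spurious low-frequency density
#' fluctuations, as real collagen fills the field uniformly), a Gaussian
#' optical blur emulating the microscope point-spread function, and additive
#' Gaussian background noise.
#'
#' @param size_px Field side in pixels, `>= 256`.
#' @param n_fibers Number of fiber segments.
#' @param kappa Axial von Mises concentration; 0 = uniform (random
#'   orientation), larger = more parallel.
#' @param mean_angle_deg Mean fiber direction in `[0, 180)`.
#' @param fiber_length_px,fiber_width_px,fiber_intensity Length-2 ranges
#'   (low, high) sampled uniformly per fiber.
#' @param background_noise_sd Additive Gaussian noise SD (8-bit scale).
#' @param psf_sigma_px Gaussian blur SD in pixels.
#' @param seed Integer seed; the generator is a pure function of it.
#' @return A `cbo_fiber_params` list.
#' @export
fiber_field_params <- function(size_px = 256L,
                               n_fibers = 512L,
                               kappa = 0,
                               mean_angle_deg = 30,
                               fiber_length_px = c(120, 250),
                               fiber_width_px = c(3, 6),
                               fiber_intensity = c(40, 90),
                               background_noise_sd = 6,
                               psf_sigma_px = 1.2,
                               seed = 1L) {
  if (size_px < 256) {
    abort("`size_px` must be at least 256.", class = "cbo_error_invalid_params")
  }
  rngs <- list(fiber_length_px = fiber_length_px, fiber_width_px = fiber_width_px,
               fiber_intensity = fiber_intensity)
  for (nm in names(rngs)) {
    r <- rngs[[nm]]
    if (length(r) != 2 || r[1] > r[2] || r[1] <= 0) {
      abort(paste0("`", nm, "` must be a positive (low, high) range."),
            class = "cbo_error_invalid_params")
    }
  }
  if (n_fibers < 1 || kappa < 0 || background_noise_sd < 0) {
    abort("invalid fiber-field parameters.", class = "cbo_error_invalid_params")
  }
  structure(list(size_px = as.integer(size_px), n_fibers = as.integer(n_fibers),
                 kappa = kappa, mean_angle_deg = mean_angle_deg %% 180,
                 fiber_length_px = fiber_length_px,
                 fiber_width_px = fiber_width_px,
                 fiber_intensity = fiber_intensity,
                 background_noise_sd = background_noise_sd,
                 psf_sigma_px = psf_sigma_px, seed = as.integer(seed)),
            class = "cbo_fiber_params")
}

# accumulate anti-aliased segments; returns the raw intensity field.
# x runs along columns and y along rows, so an angle of 0 (from the +x axis)
# is a horizontal fiber, matching the spectrum's angle convention.
render_fibers <- function(p, angles, cx, cy, L, W, A) {
  n <- p$size_px
  img <- matrix(0, n, n)
  for (i in seq_along(angles)) {
    dx <- cos(angles[i])
    dy <- sin(angles[i])
    x0 <- cx[i] - L[i] / 2 * dx
    y0 <- cy[i] - L[i] / 2 * dy
    x1 <- cx[i] + L[i] / 2 * dx
    y1 <- cy[i] + L[i] / 2 * dy
    rmin <- max(1, floor(min(y0, y1) - W[i]))
    rmax <- min(n, ceiling(max(y0, y1) + W[i]))
    cmin <- max(1, floor(min(x0, x1) - W[i]))
    cmax <- min(n, ceiling(max(x0, x1) + W[i]))
    if (rmin > rmax || cmin > cmax) next
    rr <- rmin:rmax
    cc <- cmin:cmax
    py <- matrix(rr, length(rr), length(cc))
    px <- matrix(cc, length(rr), length(cc), byrow = TRUE)
    vx <- x1 - x0
    vy <- y1 - y0
    l2 <- vx^2 + vy^2
    tt <- pmin(pmax(((px - x0) * vx + (py - y0) * vy) / l2, 0), 1)
    d <- sqrt((px - x0 - tt * vx)^2 + (py - y0 - tt * vy)^2)
    img[rr, cc] <- img[rr, cc] + A[i] * pmin(pmax(W[i] / 2 + 0.5 - d, 0), 1)
  }
  img
}

sample_fiber_geometry <- function(p) {
  nf <- p$n_fibers
  n <- p$size_px
  # axial von Mises via angle doubling
  angles <- rvonmises(nf, 2 * p$mean_angle_deg * pi / 180, p$kappa) / 2
  # stratified centers over a sqrt(nf) x sqrt(nf) grid
  g <- ceiling(sqrt(nf))
  cells <- sample(g * g, nf)
  cell <- n / g
  cx <- ((cells - 1) %% g) * cell + runif(nf, 0, cell)
  cy <- ((cells - 1) %/% g) * cell + runif(nf, 0, cell)
  list(angles = angles, cx = cx, cy = cy,
       L = runif(nf, p$fiber_length_px[1], p$fiber_length_px[2]),
       W = runif(nf, p$fiber_width_px[1], p$fiber_width_px[2]),
       A = runif(nf, p$fiber_intensity[1], p$fiber_intensity[2]))
}

#' Generate a synthetic fiber-texture image
#'
#' Draws the fiber field of [fiber_field_params()] and returns an 8-bit
#' greyscale image together with the ground-truth fiber angles (axial,
#' radians in `[0, pi)`). Deterministic given the seed.
#'
#' @param p A [fiber_field_params()] object.
#' @return A list: `image` (a [grey_image()] with 8-bit depth), `angles`
#'   (ground-truth orientations), `params`.
#' @export
generate_fiber_image <- function(p = fiber_field_params()) {
  stopifnot(inherits(p, "cbo_fiber_params"))
  set.seed(p$seed)
  geo <- sample_fiber_geometry(p)
  img <- render_fibers(p, geo$angles, geo$cx, geo$cy, geo$L, geo$W, geo$A)
  if (p$psf_sigma_px > 0) {
    img <- as.matrix(EBImage::gblur(img, sigma = p$psf_sigma_px))
  }
  img <- img / max(1, max(img)) * 235
  img <- img + rnorm(length(img), 0, p$background_noise_sd)
  img <- matrix(pmin(pmax(round(img), 0), 255), p$size_px, p$size_px)
  list(image = grey_image(img, depth = "8bit",
                          provenance = list(generator = "fiber_field",
                                            kappa = p$kappa, seed = p$seed)),
       angles = geo$angles %% pi,
       params = p)
}

#' Parameters of a synthetic Masson-like scene
#'
#' RGB rendering of a fiber field in a collagen-like blue over a pale
#' background, with purple "cellular" blobs superimposed until a target
#' coverage is approached. Blob and collagen hues are kept at least 30
#' degrees apart so the hue segmentation is well posed.
#'
#' @param kappa,seed Shortcut for the default fiber field.
#' @param fiber A [fiber_field_params()]. The scene default uses fewer
#'   fibers than the greyscale texture default because scene fibers are
#'   opaque: a moderate density leaves background and cellular blobs visible
#'   between bundles, as in a real trichrome field.
#' @param collagen_color,background_color,blob_color RGB triples (0-255).
#' @param n_cell_blobs Maximum number of blobs drawn.
#' @param blob_radius_px Length-2 range of mean blob radii.
#' @param blob_coverage_target Fraction of the field to cover with visible
#'   blob pixels, in `[0, 0.5)`; drawing stops once reached (never exceeded
#'   by more than one blob).
#' @return A `cbo_masson_params` list.
#' @export
masson_scene_params <- function(kappa = 0, seed = 1L,
                                fiber = fiber_field_params(n_fibers = 110L,
                                                           kappa = kappa,
                                                           seed = seed),
                                collagen_color = c(60, 90, 200),
                                background_color = c(235, 230, 232),
                                n_cell_blobs = 60L,
                                blob_radius_px = c(8, 18),
                                blob_color = c(170, 60, 170),
                                blob_coverage_target = 0.15) {
  hue_of <- function(col) {
    grDevices::rgb2hsv(matrix(col, 3))[1] * 360
  }
  dh <- abs(hue_of(blob_color) - hue_of(collagen_color))
  dh <- min(dh, 360 - dh)
  if (dh < 30) {
    abort("blob and collagen hues must be at least 30 degrees apart.",
          class = "cbo_error_invalid_params")
  }
  if (blob_coverage_target < 0 || blob_coverage_target >= 0.5) {
    abort("`blob_coverage_target` must lie in [0, 0.5).",
          class = "cbo_error_invalid_params")
  }
  structure(list(fiber = fiber, collagen_color = collagen_color,
                 background_color = background_color,
                 n_cell_blobs = as.integer(n_cell_blobs),
                 blob_radius_px = blob_radius_px, blob_color = blob_color,
                 blob_coverage_target = blob_coverage_target),
            class = "cbo_masson_params")
}

#' Generate a synthetic Masson-like RGB micrograph
#'
#' The cellular blobs are painted on the background layer and the collagen
#' fibers are alpha-composited over them, as in tissue where the collagen
#' bundles of the section plane overlie the cellular matrix. The returned
#' ground-truth blob mask contains the pixels where the purple layer remains
#' visible (fiber opacity below one half): exactly the pixels a hue-based
#' segmentation can and should remove.
#'
#' @param p A [masson_scene_params()] object.
#' @return A list: `image` (a `cbo_micrograph`, technique `"synthetic"`),
#'   `blob_mask` (ground-truth logical matrix of visible blob pixels),
#'   `angles` (fiber ground truth), `params`.
#' @export
generate_masson_image <- function(p = masson_scene_params()) {
  stopifnot(inherits(p, "cbo_masson_params"))
  fp <- p$fiber
  set.seed(fp$seed)
  geo <- sample_fiber_geometry(fp)
  # stained bundles are effectively opaque: render unit-intensity coverage,
  # clip, then blur by the PSF so only the anti-aliased rims are partial
  cov <- render_fibers(fp, geo$angles, geo$cx, geo$cy, geo$L, geo$W,
                       rep(1, fp$n_fibers))
  alpha <- pmin(cov, 1)
  if (fp$psf_sigma_px > 0) {
    alpha <- as.matrix(EBImage::gblur(alpha, sigma = fp$psf_sigma_px))
    alpha <- pmin(pmax(alpha, 0), 1)
  }
  n <- fp$size_px
  visible <- alpha < 0.5
  # purple blobs on the background layer, drawn until the VISIBLE coverage
  # reaches the target (never exceeded by more than one blob)
  painted <- matrix(FALSE, n, n)
  target_px <- p$blob_coverage_target * n * n
  if (p$n_cell_blobs > 0 && target_px > 0) {
    for (b in seq_len(p$n_cell_blobs)) {
      if (sum(painted & visible) >= target_px) break
      r0 <- runif(1, p$blob_radius_px[1], p$blob_radius_px[2])
      bx <- runif(1, 1, n)
      by <- runif(1, 1, n)
      ecc <- runif(1, 0.55, 1)
      th <- runif(1, 0, pi)
      ph1 <- runif(1, 0, 2 * pi)
      ph2 <- runif(1, 0, 2 * pi)
      rmax <- ceiling(r0 / ecc * 1.5)
      rr <- max(1, floor(bx - rmax)):min(n, ceiling(bx + rmax))
      cc <- max(1, floor(by - rmax)):min(n, ceiling(by + rmax))
      xx <- matrix(rr, length(rr), length(cc)) - bx
      yy <- matrix(cc, length(rr), length(cc), byrow = TRUE) - by
      u <- xx * cos(th) + yy * sin(th)
      v <- -xx * sin(th) + yy * cos(th)
      phi <- atan2(v, u)
      rad <- r0 * (1 + 0.22 * sin(3 * phi + ph1) + 0.13 * sin(5 * phi + ph2))
      inside <- (u / 1)^2 + (v / ecc)^2 <= rad^2
      # cells occupy the interstitial space and are molded around the
      # bundles: paint only where no fiber covers the pixel
      painted[rr, cc][inside & visible[rr, cc]] <- TRUE
    }
  }
  px <- array(0, c(n, n, 3))
  for (ch in 1:3) {
    layer <- matrix(p$background_color[ch], n, n)
    layer[painted] <- p$blob_color[ch]
    px[, , ch] <- layer * (1 - alpha) + p$collagen_color[ch] * alpha
  }
  noise <- rnorm(n * n, 0, fp$background_noise_sd)
  for (ch in 1:3) {
    px[, , ch] <- pmin(pmax(round(px[, , ch] + noise), 0), 255)
  }
  list(image = micrograph(px, technique = "synthetic",
                          sample_id = paste0("synthetic_", fp$seed),
                          replicate_id = 1L),
       blob_mask = painted & visible,
       angles = geo$angles %% pi,
       params = p)
}

#' Spectral second-moment anisotropy oracle
#'
#' Independent check of the orientation index's ordering behavior: computes
#' the raw power spectrum (no gain, log or threshold), excludes the DC bin,
#' forms the second-moment matrix of spectral power over centered frequency
#' coordinates and returns `sqrt(lambda_min / lambda_max)` of its
#' eigenvalues: near 1 for isotropic images, near 0 for a pure grating. Used
#' only for ordering/correlation comparisons with the pipeline, never for
#' equality.
#'
#' @param grey A [grey_image()].
#' @return A number in `(0, 1]`.
#' @export
oracle_spectral_anisotropy <- function(grey) {
  stopifnot(inherits(grey, "cbo_grey"))
  px <- grey$pixels
  if (max(px) == min(px)) {
    abort("constant image.", class = "cbo_error_degenerate_image")
  }
  n <- min(dim(px))
  r0 <- (nrow(px) - n) %/% 2
  c0 <- (ncol(px) - n) %/% 2
  px <- px[(r0 + 1):(r0 + n), (c0 + 1):(c0 + n)]
  p2 <- Mod(fftshift(fft(px - mean(px))))^2
  dc <- n %/% 2 + 1L
  p2[dc, dc] <- 0
  fr <- matrix(seq_len(n) - dc, n, n)
  fc <- matrix(seq_len(n) - dc, n, n, byrow = TRUE)
  w <- sum(p2)
  mrr <- sum(p2 * fr * fr) / w
  mcc <- sum(p2 * fc * fc) / w
  mrc <- sum(p2 * fr * fc) / w
  ev <- eigen(matrix(c(mrr, mrc, mrc, mcc), 2), symmetric = TRUE,
              only.values = TRUE)$values
  sqrt(max(0, ev[2]) / ev[1])
}

#' Simulate a rater matrix with a known population ICC
#'
#' Generates `value = subject + rater + noise` with the subject variance set
#' so the population two-way consistency/average-measures ICC,
#' `k sigma_s^2 / (k sigma_s^2 + sigma_e^2)`, equals `icc_target`.
#'
#' @param n_samples Subjects (rows), `>= 2`.
#' @param k_raters Raters (columns), `>= 2`.
#' @param icc_target Population ICC in `[0, 1)`.
#' @param seed Integer seed.
#' @param grand_mean,sigma_e,sigma_r Location, residual SD and rater-effect
#'   SD of the simulated indices.
#' @return An n x k numeric matrix with rater column names.
#' @export
make_reliability_fixture <- function(n_samples, k_raters, icc_target,
                                     seed = 1L, grand_mean = 0.6,
                                     sigma_e = 0.05, sigma_r = 0.02) {
  if (n_samples < 2 || k_raters < 2 || icc_target < 0 || icc_target >= 1) {
    abort("invalid fixture parameters.", class = "cbo_error_invalid_params")
  }
  set.seed(seed)
  sigma_s2 <- icc_target * sigma_e^2 / (k_raters * (1 - icc_target))
  s <- rnorm(n_samples, 0, sqrt(sigma_s2))
  r <- rnorm(k_raters, 0, sigma_r)
  e <- matrix(rnorm(n_samples * k_raters, 0, sigma_e), n_samples, k_raters)
  m <- grand_mean + outer(s, rep(1, k_raters)) + outer(rep(1, n_samples), r) + e
  colnames(m) <- paste0("rater", seq_len(k_raters))
  m
}
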