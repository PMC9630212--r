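#' Construct a micrograph object from pixel data
#'
#' A micrograph is an H x W x 3 array of 8-bit intensities plus acquisition
#' metadata. Greyscale input is replicated across the three channels.
#'
#' @param pixels Numeric matrix (H x W) or array (H x W x 3) with values in
#'   `[0, 255]`.
#' @param technique One of `"masson"`, `"masson_optimized"`, `"picrosirius"`,
#'   `"he_confocal"`, `"synthetic"`.
#' @param sample_id Sample identifier.
#' @param replicate_id Integer replicate (field) number within the sample,
#'   `>= 1`.
#' @param source_path Optional path the image was read from.
#' @return An object of class `cbo_micrograph`.
#' @export
micrograph <- function(pixels,
                       technique = c("synthetic", "masson", "masson_optimized",
                                     "picrosirius", "he_confocal"),
                       sample_id = "sample",
                       replicate_id = 1L,
                       source_path = "") {
  technique <- match.arg(technique)
  if (is.matrix(pixels)) {
    pixels <- array(rep(pixels, 3L), dim = c(dim(pixels), 3L))
  }
  if (length(dim(pixels)) != 3 || dim(pixels)[3] != 3) {
    abort("`pixels` must be an H x W matrix or H x W x 3 array.",
          class = "cbo_error_unreadable_image")
  }
  d <- dim(pixels)
  if (d[1] < 64 || d[2] < 64) {
    abort(sprintf("image is %d x %d; fields smaller than 64 x 64 are rejected.",
                  d[1], d[2]),
          class = "cbo_error_image_too_small")
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    abort("pixel values must lie in [0, 255].", class = "cbo_error_unreadable_image")
  }
  if (!is.numeric(replicate_id) || replicate_id < 1) {
    abort("`replicate_id` must be an integer >= 1.", class = "cbo_error_unreadable_image")
  }
  structure(
    list(pixels = pixels, technique = technique,
         sample_id = as.character(sample_id),
         replicate_id = as.integer(replicate_id),
         source_path = as.character(source_path)),
    class = "cbo_micrograph"
  )
}

#' Read a micrograph from a TIFF or PNG file
#'
#' Greyscale files are replicated to three identical channels; 16-bit input is
#' linearly rescaled to the 0-255 working range (acquisition uses the full
#' 8-bit dynamic range, so nothing is lost at measurement scale).
#'
#' @inheritParams micrograph
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @return A `cbo_micrograph`.
#' @export
load_micrograph <- function(path,
                            technique = c("synthetic", "masson", "masson_optimized",
                                          "picrosirius", "he_confocal"),
                            sample_id = NULL,
                            replicate_id = 1L) {
  technique <- match.arg(technique)
  if (!file.exists(path)) {
    abort(paste0("file not found: ", path), class = "cbo_error_unreadable_image")
  }
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(
    switch(ext,
           "png" = png::readPNG(path),
           "tif" = ,
           "tiff" = tiff::readTIFF(path),
           abort(paste0("unsupported image format: .", ext),
                 class = "cbo_error_unreadable_image")),
    error = function(e) {
      if (inherits(e, "cbo_error_unreadable_image")) stop(e)
      abort(paste0("could not decode image ", path, ": ", conditionMessage(e)),
            class = "cbo_error_unreadable_image")
    }
  )
  # readPNG/readTIFF return [0,1] doubles; drop alpha if present
  if (length(dim(img)) == 3 && dim(img)[3] >= 3) {
    img <- img[, , 1:3, drop = FALSE]
  } else if (length(dim(img)) == 3 && dim(img)[3] == 2) {
    img <- img[, , 1, drop = TRUE]
  } else if (length(dim(img)) == 3 && dim(img)[3] == 1) {
    img <- img[, , 1, drop = TRUE]
  }
  px <- img * 255
  if (is.null(sample_id)) {
    sample_id <- tools::file_path_sans_ext(basename(path))
  }
  micrograph(px, technique = technique, sample_id = sample_id,
             replicate_id = replicate_id, source_path = path)
}

#' @export
print.cbo_micrograph <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<cbo_micrograph> %d x %d, technique %s, sample %s, replicate %d\n",
              d[1], d[2], x$technique, x$sample_id, x$replicate_id))
  invisible(x)
}

#' Convert a micrograph to greyscale
#'
#' Uses the Rec. 601 luminance weights (0.299 R + 0.587 G + 0.114 B) and
#' rescales to the declared working depth. A channel-replicated greyscale
#' image passes through unchanged (up to the depth rescale).
#'
#' @param img A `cbo_micrograph`.
#' @param depth `"16bit"` (0-65535 working range, the default measurement
#'   depth) or `"8bit"` (0-255).
#' @return An object of class `cbo_grey`: a list with `pixels` (H x W
#'   matrix), `depth` and `provenance`.
#' @export
to_grey <- function(img, depth = c("16bit", "8bit")) {
  depth <- match.arg(depth)
  stopifnot(inherits(img, "cbo_micrograph"))
  lum <- 0.299 * img$pixels[, , 1] + 0.587 * img$pixels[, , 2] +
    0.114 * img$pixels[, , 3]
  scale <- if (depth == "16bit") 65535 / 255 else 1
  grey_image(lum * scale, depth = depth,
             provenance = list(technique = img$technique,
                               sample_id = img$sample_id,
                               replicate_id = img$replicate_id))
}

#' Construct a greyscale image object
#'
#' @param pixels H x W numeric matrix of non-negative values within the
#'   declared depth range.
#' @param depth `"16bit"` or `"8bit"`.
#' @param provenance Optional metadata list carried along the pipeline.
#' @return A `cbo_grey` object.
#' @export
grey_image <- function(pixels, depth = c("16bit", "8bit"), provenance = list()) {
  depth <- match.arg(depth)
  stopifnot(is.matrix(pixels), is.numeric(pixels))
  dmax <- depth_max(depth)
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > dmax) {
    abort(sprintf("grey values must lie in [0, %d] for %s depth.", dmax, depth),
          class = "cbo_error_unreadable_image")
  }
  structure(list(pixels = pixels, depth = depth, provenance = provenance),
            class = "cbo_grey")
}

depth_max <- function(depth) if (depth == "16bit") 65535 else 255

#' @export
print.cbo_grey <- function(x, ...) {
  cat(sprintf("<cbo_grey> %d x %d, %s, range [%.1f, %.1f]\n",
              nrow(x$pixels), ncol(x$pixels), x$depth,
              min(x$pixels), max(x$pixels)))
  invisible(x)
}
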