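spectrum_raster_df <- function(values) {
  tibble(
    row = rep(seq_len(nrow(values)), times = ncol(values)),
    col = rep(seq_len(ncol(values)), each = nrow(values)),
    value = as.vector(values)
  )
}

#' Display a power plot
#'
#' @param object A `cbo_spectrum`.
#' @param ... Unused.
#' @return A ggplot raster of the 0-255 power plot.
#' @export
autoplot.cbo_spectrum <- function(object, ...) {
  df <- spectrum_raster_df(object$values)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255), name = "power") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Power plot (gain %g, %s window)",
                                  object$gain, object$window))
}

#' Display a segmented power plot
#'
#' @param object A `cbo_mask`.
#' @param ... Unused.
#' @return A ggplot raster of the binary mask.
#' @export
autoplot.cbo_mask <- function(object, ...) {
  df <- spectrum_raster_df(object$mask * 1)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = factor(.data$value))) +
    ggplot2::geom_raster(show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(`0` = "black", `1` = "white")) +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("Segmented plot (threshold %d, %d px)",
                                  object$threshold_used, object$area_px))
}
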