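#' Intraclass correlation: two-way random effects, consistency, average
#' measures
#'
#' From the two-way ANOVA without replication (rows = subjects/samples,
#' columns = raters or techniques): with `MS_R` the between-subjects mean
#' square and `MS_E` the residual mean square,
#' \deqn{ICC = (MS_R - MS_E) / MS_R.}
#' The F statistic is `MS_R / MS_E` with `n - 1` and `(n - 1)(k - 1)` degrees
#' of freedom; the p-value is the one-sided upper tail (H0: ICC = 0), and the
#' confidence interval is the standard F-based interval
#' `[1 - 1/F_L, 1 - 1/F_U]` with `F_L = F / qf(1 - alpha/2, df1, df2)` and
#' `F_U = F * qf(1 - alpha/2, df2, df1)`.
#'
#' @param m Numeric matrix or data frame, n samples x k raters/methods, no
#'   missing cells; n >= 2, k >= 2 (a warning is given for n < 5).
#' @param alpha Two-sided confidence level parameter (default 0.05 for a 95%
#'   CI).
#' @return A `cbo_icc` object: `icc`, `ci_low`, `ci_high`, `f_value`, `df1`,
#'   `df2`, `p_value`, `n`, `k`.
#' @examples
#' m <- cbind(r1 = c(.2, .4, .6, .5, .8), r2 = c(.3, .5, .7, .6, .9))
#' icc_consistency_average(m)
#' @export
icc_consistency_average <- function(m, alpha = 0.05) {
  m <- as.matrix(m)
  storage.mode(m) <- "double"
  if (anyNA(m)) abort("rater matrix has missing cells.", class = "cbo_error_unpaired")
  n <- nrow(m)
  k <- ncol(m)
  if (n < 2) abort("need at least 2 subjects.", class = "cbo_error_too_few_subjects")
  if (k < 2) abort("need at least 2 raters/methods.", class = "cbo_error_too_few_subjects")
  if (n < 5) warn(sprintf("only %d subjects; ICC will be unstable.", n))

  grand <- mean(m)
  row_means <- rowMeans(m)
  col_means <- colMeans(m)
  ss_rows <- k * sum((row_means - grand)^2)
  ss_cols <- n * sum((col_means - grand)^2)
  ss_tot <- sum((m - grand)^2)
  ss_err <- ss_tot - ss_rows - ss_cols
  # a residual at rounding-noise level is exactly zero (identical columns up
  # to an additive constant must give ICC = 1 exactly)
  if (ss_err < 1e-12 * max(ss_tot, 1e-300)) ss_err <- 0
  ms_r <- ss_rows / (n - 1)
  ms_e <- ss_err / ((n - 1) * (k - 1))
  if (ms_r <= 0) abort("no between-subject variance; ICC undefined.",
                       class = "cbo_error_zero_variance")
  icc <- (ms_r - ms_e) / ms_r
  f <- if (ms_e > 0) ms_r / ms_e else Inf
  df1 <- n - 1
  df2 <- (n - 1) * (k - 1)
  p <- pf(f, df1, df2, lower.tail = FALSE)
  fl <- f / qf(1 - alpha / 2, df1, df2)
  fu <- f * qf(1 - alpha / 2, df2, df1)
  structure(list(icc = icc, ci_low = 1 - 1 / fl, ci_high = 1 - 1 / fu,
                 f_value = f, df1 = df1, df2 = df2, p_value = p,
                 n = n, k = k, alpha = alpha),
            class = "cbo_icc")
}

#' @export
print.cbo_icc <- function(x, ...) {
  cat(sprintf("ICC (two-way random, consistency, average measures) = %.3f [%.3f, %.3f], F(%d, %d) = %.2f, p = %.3g\n",
              x$icc, x$ci_low, x$ci_high, x$df1, x$df2, x$f_value, x$p_value))
  invisible(x)
}

#' @export
tidy.cbo_icc <- function(x, ...) {
  tibble(icc = x$icc, ci_low = x$ci_low, ci_high = x$ci_high,
         f_value = x$f_value, df1 = x$df1, df2 = x$df2, p_value = x$p_value)
}

#' @export
glance.cbo_icc <- function(x, ...) {
  tibble(icc = x$icc, p_value = x$p_value, n = x$n, k = x$k)
}

#' Bland-Altman agreement analysis
#'
#' Differences `x - y` against pairwise means; the bias is the mean
#' difference and the limits of agreement are the bias plus or minus two
#' standard deviations of the differences (the conventional interval expected
#' to contain about 95% of differences).
#'
#' @param x,y Equal-length numeric vectors of paired measurements, n >= 2.
#' @return A `cbo_bland_altman`: `bias`, `sd_diff`, `loa_low`, `loa_high`,
#'   `n`, and `data` (tibble of per-pair `mean` and `difference` for
#'   plotting).
#' @examples
#' bland_altman(c(1, 2, 3), c(0, 2, 4))
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) {
    abort("x and y must have equal length.", class = "cbo_error_length_mismatch")
  }
  if (length(x) < 2) {
    abort("need at least 2 pairs.", class = "cbo_error_too_few_points")
  }
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  structure(list(bias = bias, sd_diff = s,
                 loa_low = bias - 2 * s, loa_high = bias + 2 * s,
                 n = length(d),
                 data = tibble(mean = (x + y) / 2, difference = d)),
            class = "cbo_bland_altman")
}

#' @export
print.cbo_bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: bias %.4f, SD %.4f, limits of agreement [%.4f, %.4f] (n = %d)\n",
              x$bias, x$sd_diff, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' @export
tidy.cbo_bland_altman <- function(x, ...) {
  tibble(bias = x$bias, sd_diff = x$sd_diff,
         loa_low = x$loa_low, loa_high = x$loa_high, n = x$n)
}

#' @rdname bland_altman
#' @param object A `cbo_bland_altman` object.
#' @param ... Unused.
#' @export
autoplot.cbo_bland_altman <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = .data$mean, y = .data$difference)) +
    ggplot2::annotate("rect", xmin = -Inf, xmax = Inf,
                      ymin = object$loa_low, ymax = object$loa_high,
                      alpha = 0.12) +
    ggplot2::geom_hline(yintercept = object$bias) +
    ggplot2::geom_hline(yintercept = c(object$loa_low, object$loa_high),
                        linetype = "dashed") +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Mean of the two measurements",
                  y = "Difference between measurements",
                  title = sprintf("Bias %.3f, limits of agreement [%.3f, %.3f]",
                                  object$bias, object$loa_low, object$loa_high))
}

#' Coefficient of variation from the standard error of measurement
#'
#' `SEmeas = s_pooled * sqrt(1 - ICC)` where `s_pooled` is the standard
#' deviation of all n x k values and ICC is the consistency/average-measures
#' intraclass correlation of the matrix; then
#' `CV% = 100 * SEmeas / grand mean`. Lower values indicate higher
#' consistency between the measurement sets.
#'
#' @inheritParams icc_consistency_average
#' @return A `cbo_cv`: `cv_percent`, `se_meas`, `grand_mean`, `icc`.
#' @export
coefficient_of_variation <- function(m) {
  m <- as.matrix(m)
  grand <- mean(m)
  if (grand <= 0) {
    abort("grand mean must be positive for a coefficient of variation.",
          class = "cbo_error_zero_mean")
  }
  icc <- icc_consistency_average(m)$icc
  s_pooled <- sd(as.vector(m))
  se_meas <- s_pooled * sqrt(max(0, 1 - icc))
  structure(list(cv_percent = 100 * se_meas / grand, se_meas = se_meas,
                 grand_mean = grand, icc = icc),
            class = "cbo_cv")
}

#' @export
print.cbo_cv <- function(x, ...) {
  cat(sprintf("CV = %.2f%% (SEmeas = %.4f, grand mean = %.4f)\n",
              x$cv_percent, x$se_meas, x$grand_mean))
  invisible(x)
}

#' Histogram of CBO index values over half-open bins
#'
#' Counts over bins `[origin + i w, origin + (i + 1) w)`; a value exactly on
#' a bin edge belongs to the right (higher) bin. The total count equals the
#' number of inputs.
#'
#' @param values Non-empty numeric vector.
#' @param bin_width Bin width in `(0, 1]`.
#' @param origin Left edge of the bin grid.
#' @return A tibble with `bin_center` and `count` (only non-empty bins).
#' @export
index_histogram <- function(values, bin_width = 0.05, origin = 0) {
  if (length(values) == 0) {
    abort("no values to bin.", class = "cbo_error_empty_input")
  }
  if (bin_width <= 0 || bin_width > 1) {
    abort("`bin_width` must lie in (0, 1].", class = "cbo_error_invalid_config")
  }
  i <- floor((values - origin) / bin_width + 1e-12)
  tab <- table(i)
  tibble(bin_center = origin + (as.numeric(names(tab)) + 0.5) * bin_width,
         count = as.integer(tab))
}

#' Histogram plot of index distributions
#'
#' @param values Numeric vector of (non-averaged) index measurements.
#' @inheritParams index_histogram
#' @return A ggplot.
#' @export
plot_index_histogram <- function(values, bin_width = 0.05, origin = 0) {
  h <- index_histogram(values, bin_width, origin)
  ggplot2::ggplot(h, ggplot2::aes(x = .data$bin_center, y = .data$count)) +
    ggplot2::geom_col(width = bin_width * 0.92) +
    ggplot2::labs(x = "CBO index", y = "Count")
}

#' Pairwise reliability report
#'
#' For every pair of columns of a wide table of per-sample mean indices
#' (sample rows, one column per rater or technique), computes the
#' consistency/average-measures ICC with its confidence interval and
#' p-value, the Bland-Altman bias and limits of agreement, and the CV% with
#' its SEmeas - one row per pair, mirroring the layout of interrater and
#' intertechnique reliability tables.
#'
#' @param wide A data frame whose first column is `sample_id` and remaining
#'   columns are numeric mean indices per rater/technique, or a path to such
#'   a CSV. Missing cells raise an error naming the offending column.
#' @param alpha Confidence parameter for the ICC interval.
#' @return A tibble with columns `pair`, `icc`, `ci_low`, `ci_high`,
#'   `p_value`, `bias`, `loa_low`, `loa_high`, `cv_percent`, `se_meas`.
#' @export
reliability_report <- function(wide, alpha = 0.05) {
  if (is.character(wide)) {
    wide <- readr::read_csv(wide, show_col_types = FALSE, progress = FALSE)
  }
  stopifnot(is.data.frame(wide), ncol(wide) >= 3)
  value_cols <- names(wide)[-1]
  vals <- as.matrix(wide[value_cols])
  if (anyNA(vals)) {
    bad <- value_cols[colSums(is.na(vals)) > 0]
    abort(paste0("sample(s) missing in column(s): ", paste(bad, collapse = ", ")),
          class = "cbo_error_unpaired")
  }
  pairs <- utils::combn(value_cols, 2, simplify = FALSE)
  purrr::map_dfr(pairs, function(pr) {
    a <- vals[, pr[1]]
    b <- vals[, pr[2]]
    ic <- icc_consistency_average(cbind(a, b), alpha = alpha)
    ba <- bland_altman(a, b)
    cv <- coefficient_of_variation(cbind(a, b))
    tibble(pair = paste(pr[1], "vs.", pr[2]),
           icc = ic$icc, ci_low = ic$ci_low, ci_high = ic$ci_high,
           p_value = ic$p_value,
           bias = ba$bias, loa_low = ba$loa_low, loa_high = ba$loa_high,
           cv_percent = cv$cv_percent, se_meas = cv$se_meas)
  })
}

#' Pivot a long measurement table to the wide per-sample layout
#'
#' Averages replicates per sample within each technique (or rater label) and
#' spreads techniques into columns, the input layout of
#' [reliability_report()].
#'
#' @param records Measurement tibble with `sample_id`, `technique`, `index`.
#' @param by Column to spread (default `"technique"`).
#' @return A wide tibble: `sample_id` then one column per level of `by`.
#' @export
measurements_to_wide <- function(records, by = "technique") {
  stopifnot(is.data.frame(records), all(c("sample_id", by, "index") %in% names(records)))
  records |>
    dplyr::group_by(.data$sample_id, .data[[by]]) |>
    dplyr::summarise(mean_index = mean(.data$index), .groups = "drop") |>
    tidyr::pivot_wider(names_from = dplyr::all_of(by),
                       values_from = "mean_index")
}
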