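test_that("an additive rater shift gives ICC exactly 1", {
  x <- c(0.2, 0.35, 0.5, 0.62, 0.8, 0.44)
  res <- icc_consistency_average(cbind(x, x + 0.1))
  expect_identical(res$icc, 1)
  expect_identical(res$p_value, 0)
  expect_equal(res$ci_low, 1)
  expect_equal(res$ci_high, 1)
})

test_that("ICC matches the from-definitions ANOVA oracle and aov", {
  m <- matrix(c(0.31, 0.52, 0.44, 0.60, 0.77, 0.25,
                0.35, 0.50, 0.49, 0.66, 0.70, 0.29), ncol = 2)
  res <- icc_consistency_average(m)
  expect_equal(res$icc, icc_oracle(m), tolerance = 1e-10)

  # cross-check mean squares against stats::aov on the long layout
  long <- data.frame(y = as.vector(m),
                     subject = factor(rep(1:6, 2)),
                     rater = factor(rep(1:2, each = 6)))
  tab <- summary(stats::aov(y ~ subject + rater, data = long))[[1]]
  ms_r <- tab["subject", "Mean Sq"]
  ms_e <- tab["Residuals", "Mean Sq"]
  expect_equal(res$icc, (ms_r - ms_e) / ms_r, tolerance = 1e-10)
  expect_equal(res$f_value, ms_r / ms_e, tolerance = 1e-10)
})

test_that("ICC is invariant to per-column shifts and global affine maps", {
  set.seed(20)
  m <- matrix(rnorm(30, 0.5, 0.1), 10, 3)
  base <- icc_consistency_average(m)$icc
  shifted <- m
  shifted[, 2] <- shifted[, 2] + 0.3
  expect_equal(icc_consistency_average(shifted)$icc, base, tolerance = 1e-12)
  expect_equal(icc_consistency_average(2.5 * m - 0.7)$icc, base, tolerance = 1e-12)
})

test_that("independent columns give near-zero ICC; CI brackets the estimate", {
  set.seed(31)
  iccs <- replicate(5, icc_consistency_average(matrix(rnorm(2000), 1000, 2))$icc)
  expect_true(all(abs(iccs) < 0.15))

  for (i in 1:200) {
    n <- sample(5:30, 1)
    k <- sample(2:4, 1)
    m <- matrix(rnorm(n * k, 0.5, 0.2), n, k) +
      rnorm(n, 0, runif(1, 0, 0.3))
    r <- icc_consistency_average(m)
    expect_lte(r$ci_low, r$icc)
    expect_lte(r$icc, r$ci_high)
  }

  expect_error(icc_consistency_average(matrix(1:2, 1, 2)),
               class = "cbo_error_too_few_subjects")
  expect_error(icc_consistency_average(matrix(rep(c(1, 2), 5), 5, 2, byrow = TRUE)),
               class = "cbo_error_zero_variance")
})

test_that("the ICC estimator recovers the population value of the fixture", {
  m <- make_reliability_fixture(500, 2, icc_target = 0.95, seed = 4)
  expect_equal(icc_consistency_average(m)$icc, 0.95, tolerance = 0.02)
  m0 <- make_reliability_fixture(500, 2, icc_target = 0, seed = 4)
  expect_lt(abs(icc_consistency_average(m0)$icc), 0.2)

  # Monte-Carlo calibration: mean estimate tracks k*s^2/(k*s^2 + e^2)
  est <- vapply(1:400, function(s) {
    icc_consistency_average(make_reliability_fixture(50, 2, 0.7, seed = s))$icc
  }, numeric(1))
  expect_equal(mean(est), 0.7, tolerance = 0.02)
  expect_identical(make_reliability_fixture(20, 2, 0.5, seed = 1),
                   make_reliability_fixture(20, 2, 0.5, seed = 1))
})

test_that("Bland-Altman bias and +-2 SD limits", {
  same <- bland_altman(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$bias, 0)
  expect_equal(same$sd_diff, 0)
  expect_equal(c(same$loa_low, same$loa_high), c(0, 0))

  ba <- bland_altman(c(1, 2, 3), c(0, 2, 4))
  expect_equal(ba$bias, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(ba$loa_low, -2)
  expect_equal(ba$loa_high, 2)
  expect_equal(ba$data$mean, c(0.5, 2, 3.5))
  expect_equal(ba$data$difference, c(1, 0, -1))

  expect_error(bland_altman(1:3, 1:4), class = "cbo_error_length_mismatch")
  expect_error(bland_altman(1, 1), class = "cbo_error_too_few_points")
})

test_that("CV chains SEmeas = s_pooled * sqrt(1 - ICC) and is scale-free", {
  m <- matrix(c(0.31, 0.52, 0.44, 0.60, 0.77, 0.25,
                0.35, 0.50, 0.49, 0.66, 0.70, 0.29), ncol = 2)
  cv <- coefficient_of_variation(m)
  icc <- icc_consistency_average(m)$icc
  expect_equal(cv$se_meas, sd(as.vector(m)) * sqrt(1 - icc), tolerance = 1e-10)
  expect_equal(cv$cv_percent, 100 * cv$se_meas / mean(m), tolerance = 1e-10)
  expect_equal(coefficient_of_variation(3 * m)$cv_percent, cv$cv_percent,
               tolerance = 1e-10)
  x <- c(0.2, 0.4, 0.6, 0.5, 0.7)
  expect_equal(coefficient_of_variation(cbind(x, x))$cv_percent, 0)
  expect_error(coefficient_of_variation(m - 1), class = "cbo_error_zero_mean")
})

test_that("index histogram uses half-open bins and preserves counts", {
  h <- index_histogram(c(0.1, 0.1, 0.9), bin_width = 0.5, origin = 0)
  expect_equal(h$bin_center, c(0.25, 0.75))
  expect_equal(h$count, c(2L, 1L))

  set.seed(8)
  v <- runif(137)
  expect_equal(sum(index_histogram(v, 0.05)$count), 137L)

  # a value exactly on an edge goes to the right bin
  edge <- index_histogram(c(0.5), bin_width = 0.5, origin = 0)
  expect_equal(edge$bin_center, 0.75)
  expect_error(index_histogram(numeric(0), 0.05), class = "cbo_error_empty_input")
})

test_that("pairwise reliability report mirrors the agreement-table layout", {
  set.seed(12)
  base <- runif(21, 0.3, 0.9)
  wide <- tibble::tibble(sample_id = sprintf("s%02d", 1:21),
                         masson = base,
                         masson_optimized = base + rnorm(21, 0, 0.03),
                         picrosirius = base + rnorm(21, 0, 0.05),
                         he_confocal = base + rnorm(21, 0, 0.05))
  rep4 <- reliability_report(wide)
  expect_equal(nrow(rep4), 6L)  # all pairwise comparisons of four techniques
  expect_named(rep4, c("pair", "icc", "ci_low", "ci_high", "p_value", "bias",
                       "loa_low", "loa_high", "cv_percent", "se_meas"))

  perfect <- reliability_report(wide[c("sample_id", "masson", "masson")])
  expect_equal(perfect$icc, 1)
  expect_equal(perfect$loa_low, 0)
  expect_equal(perfect$cv_percent, 0)

  wide$picrosirius[3] <- NA
  expect_error(reliability_report(wide), class = "cbo_error_unpaired")
})

test_that("long measurement tables pivot to the wide per-sample layout", {
  rec <- tibble::tibble(
    sample_id = rep(c("a", "b"), each = 4),
    technique = rep(c("masson", "masson", "picrosirius", "picrosirius"), 2),
    index = c(0.2, 0.4, 0.5, 0.7, 0.3, 0.5, 0.6, 0.8))
  w <- measurements_to_wide(rec)
  expect_equal(dim(w), c(2L, 3L))
  expect_equal(w$masson, c(0.3, 0.4))
  expect_equal(w$picrosirius, c(0.6, 0.7))
})
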