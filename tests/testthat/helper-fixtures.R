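# shared fixtures, built in code at test time

# small RGB micrograph: blue "fiber" stripes over pale background with an
# optional magenta square blob, all hues exactly known
toy_masson_array <- function(n = 96, blob = TRUE, blob_frac = 0.1) {
  px <- array(0, c(n, n, 3))
  bg <- c(235, 230, 232)
  fib <- c(60, 90, 200)
  for (ch in 1:3) px[, , ch] <- bg[ch]
  stripe <- (seq_len(n) %% 8) < 3
  for (ch in 1:3) {
    plane <- px[, , ch]
    plane[stripe, ] <- fib[ch]
    px[, , ch] <- plane
  }
  if (blob) {
    side <- round(sqrt(blob_frac) * n)
    rows <- 10:(10 + side - 1)
    cols <- 20:(20 + side - 1)
    purple <- c(170, 60, 170)  # hue 300
    for (ch in 1:3) {
      plane <- px[, , ch]
      plane[rows, cols] <- purple[ch]
      px[, , ch] <- plane
    }
    attr(px, "blob") <- list(rows = rows, cols = cols)
  }
  px
}

random_grey <- function(n = 64, seed = 42) {
  set.seed(seed)
  grey_image(matrix(round(runif(n * n, 0, 255)), n, n), depth = "8bit")
}

# independent Otsu oracle: brute force over every split point, maximizing
# the between-class variance of the rounded non-zero values
otsu_oracle <- function(values) {
  x <- as.integer(round(values[values > 0]))
  best <- -Inf
  best_t <- 0L
  for (t in 1:255) {
    lo <- x[x < t]
    hi <- x[x >= t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(x)
    w1 <- 1 - w0
    sb <- w0 * w1 * (mean(lo) - mean(hi))^2
    if (sb > best + 1e-12) {
      best <- sb
      best_t <- t
    }
  }
  best_t
}

# from-definitions two-way ANOVA ICC oracle: explicit double loops
icc_oracle <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  grand <- 0
  for (i in 1:n) for (j in 1:k) grand <- grand + m[i, j]
  grand <- grand / (n * k)
  ss_rows <- 0
  for (i in 1:n) {
    rm <- 0
    for (j in 1:k) rm <- rm + m[i, j]
    rm <- rm / k
    ss_rows <- ss_rows + k * (rm - grand)^2
  }
  ss_cols <- 0
  for (j in 1:k) {
    cm <- 0
    for (i in 1:n) cm <- cm + m[i, j]
    cm <- cm / n
    ss_cols <- ss_cols + n * (cm - grand)^2
  }
  ss_tot <- 0
  for (i in 1:n) for (j in 1:k) ss_tot <- ss_tot + (m[i, j] - grand)^2
  ms_r <- ss_rows / (n - 1)
  ms_e <- (ss_tot - ss_rows - ss_cols) / ((n - 1) * (k - 1))
  (ms_r - ms_e) / ms_r
}
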