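# Shared fixtures: small scan dimensions keep the suite fast; the
# full-frame 32x512 geometry is exercised where the contract demands it.

small_spec <- function(n_melanoma = 2L, n_benign = 3L, ...) {
  args <- list(...)
  defaults <- list(
    n_rows = 16L, n_cols = 64L, peak_row = 8L,
    effect_size = 1, noise_rate = 0, subject_shift_sd = 0.05, seed = 99L
  )
  defaults[names(args)] <- args
  do.call(cohort_spec, c(list(n_melanoma, n_benign), defaults))
}

small_cohort <- function(...) generate_cohort(small_spec(...))

random_scan_matrix <- function(n_rows = 8L, n_cols = 12L) {
  matrix(runif(n_rows * n_cols, 0, 100), n_rows, n_cols)
}

# independent brute-force oracle for the five image statistics
brute_stats <- function(m) {
  vals <- as.numeric(m)
  n <- length(vals)
  mu <- 0
  for (v in vals) mu <- mu + v
  mu <- mu / n
  ss <- 0; ad <- 0; a1 <- 0; s2 <- 0
  for (v in vals) {
    ss <- ss + (v - mu)^2
    ad <- ad + abs(v - mu)
    a1 <- a1 + abs(v)
    s2 <- s2 + v^2
  }
  c(mean = mu, sd = sqrt(ss / n), mad = ad / n, l1 = a1, l2 = sqrt(s2))
}

# independent brute-force oracle for the reflection-padded median filter
brute_median_filter <- function(m, wr, wc) {
  nr <- nrow(m); nc <- ncol(m)
  reflect <- function(idx, n) {
    while (idx < 1 || idx > n) {
      if (idx < 1) idx <- 1 - idx
      if (idx > n) idx <- 2 * n + 1 - idx
    }
    idx
  }
  out <- m
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      win <- numeric(0)
      for (di in -(wr %/% 2):(wr %/% 2)) {
        for (dj in -(wc %/% 2):(wc %/% 2)) {
          win <- c(win, m[reflect(i + di, nr), reflect(j + dj, nc)])
        }
      }
      out[i, j] <- median(win)
    }
  }
  out
}

# feature table of iid noise with a shifted positive class, for
# classifier tests that need named 10-feature columns
toy_feature_table <- function(n_pos = 10L, n_neg = 20L, shift = 3, seed = 1L) {
  set.seed(seed)
  d <- 10L
  x <- rbind(
    matrix(rnorm(n_pos * d, mean = shift), n_pos, d),
    matrix(rnorm(n_neg * d, mean = 0), n_neg, d)
  )
  df <- data.frame(
    sample_id = sprintf("s%03d", seq_len(n_pos + n_neg)),
    label = c(rep(1, n_pos), rep(-1, n_neg))
  )
  cols <- c("p_mean", "p_sd", "p_mad", "p_l1", "p_l2",
            "v_mean", "v_sd", "v_mad", "v_l1", "v_l2")
  df[cols] <- as.data.frame(x)
  df
}
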