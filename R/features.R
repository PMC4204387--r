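#' Statistical summary of a corrected image
#'
#' The five statistics that summarize the pixel-intensity distribution
#' of one corrected image `I` with `m x n` pixels:
#'
#' * `mean`: \eqn{\mu = \frac{1}{mn}\sum_{ij} I_{ij}}
#' * `sd`: population standard deviation,
#'   \eqn{\sigma = \sqrt{\frac{1}{mn}\sum_{ij}(I_{ij}-\mu)^2}}
#'   (divisor `m*n`, not `m*n - 1`)
#' * `mad`: mean absolute deviation,
#'   \eqn{\frac{1}{mn}\sum_{ij}|I_{ij}-\mu|}
#' * `l1`: \eqn{\sum_{ij}|I_{ij}|}
#' * `l2`: \eqn{\sqrt{\sum_{ij} I_{ij}^2}}
#'
#' Statistics are computed on the signed corrected values; no clipping
#' is applied (the absolute values and squares handle sign where it
#' matters).
#'
#' @param x A `corrected_image` or numeric matrix of finite values.
#' @return Named numeric vector `c(mean, sd, mad, l1, l2)` of class
#'   `scan_stats`.
#' @export
#' @examples
#' scan_stats(matrix(c(0.2, 0.4, -0.2, 0), 2, 2))
scan_stats <- function(x) {
  m <- if (inherits(x, "corrected_image")) x$values else x
  if (!is.matrix(m) || !is.numeric(m) || length(m) == 0L) {
    stop("`x` must be a non-empty numeric matrix or corrected_image",
         call. = FALSE)
  }
  if (anyNA(m) || any(!is.finite(m))) {
    stop("`x` contains non-finite values", call. = FALSE)
  }
  n_px <- length(m)
  mu <- sum(m) / n_px
  dev <- m - mu
  structure(
    c(
      mean = mu,
      sd = sqrt(sum(dev^2) / n_px),
      mad = sum(abs(dev)) / n_px,
      l1 = sum(abs(m)),
      l2 = sqrt(sum(m^2))
    ),
    class = "scan_stats"
  )
}

#' @export
print.scan_stats <- function(x, ...) {
  cat("<scan_stats>\n")
  print(unclass(x), ...)
  invisible(x)
}

#' Build the 10-dimensional feature vector of a sample
#'
#' Preprocesses the six scans ([preprocess_sample()]) and computes the
#' five statistics ([scan_stats()]) on the corrected P image and the
#' corrected V image. The fixed column order is
#' `p_mean, p_sd, p_mad, p_l1, p_l2, v_mean, v_sd, v_mad, v_l1, v_l2`.
#'
#' @param sample A [sample_record()].
#' @param window Median-filter window.
#' @return One-row data frame: `sample_id`, `label` (+1/-1/NA coding)
#'   and the 10 feature columns.
#' @export
build_feature_vector <- function(sample, window = c(3L, 3L)) {
  corr <- preprocess_sample(sample, window)
  p <- scan_stats(corr$P)
  v <- scan_stats(corr$V)
  out <- data.frame(
    sample_id = sample$sample_id,
    label = sample$label,
    t(c(unclass(p), unclass(v))),
    stringsAsFactors = FALSE
  )
  names(out) <- c("sample_id", "label", FEATURE_COLUMNS)
  rownames(out) <- NULL
  out
}

#' Featurize a whole cohort
#'
#' Applies [build_feature_vector()] to every sample of a cohort (a list
#' of [sample_record()]s or a manifest CSV path), preserving input
#' order. A failure in any sample aborts the run, reporting the
#' offending `sample_id`. Unknown-label samples are allowed (diagnosis
#' path).
#'
#' @param x List of sample records, or path to a manifest CSV.
#' @param window Median-filter window.
#' @param n_rows,n_cols Scan dimensions (only used when reading a
#'   manifest).
#' @return Data frame, one row per sample, columns `sample_id`, `label`
#'   and the 10 features.
#' @export
featurize_cohort <- function(x, window = c(3L, 3L),
                             n_rows = 32L, n_cols = 512L) {
  if (is.character(x) && length(x) == 1L) {
    x <- read_manifest(x, n_rows = n_rows, n_cols = n_cols)
  }
  stopifnot(is.list(x))
  rows <- lapply(x, function(sample) {
    tryCatch(
      build_feature_vector(sample, window),
      error = function(e) {
        stop("featurization failed for sample ",
             if (inherits(sample, "sample_record")) sample$sample_id else "?",
             ": ", conditionMessage(e), call. = FALSE)
      }
    )
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) {
    out <- data.frame(
      sample_id = character(), label = numeric(),
      matrix(numeric(), 0, 10, dimnames = list(NULL, FEATURE_COLUMNS)),
      stringsAsFactors = FALSE
    )
  }
  rownames(out) <- NULL
  out
}

# column names for a feature subset: "p", "v" or "pv"
feature_set_columns <- function(feature_set = c("pv", "p", "v")) {
  feature_set <- match.arg(feature_set)
  switch(feature_set,
    pv = FEATURE_COLUMNS,
    p = FEATURE_COLUMNS[1:5],
    v = FEATURE_COLUMNS[6:10]
  )
}
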