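#' Specify a repeated random-split experiment
#'
#' The evaluation protocol: the labelled cohort is repeatedly divided
#' into a training set of `n_train` samples and a test set of the rest
#' by random sampling without replacement, a classifier is trained and
#' tested on each split, and the per-run sensitivity/specificity/
#' accuracy are averaged. With `stratified = TRUE` (default) the train
#' set preserves the cohort's class proportions (half-up rounding), so
#' every test set of a 19/168 cohort at `n_train = 60` contains exactly
#' 13 melanoma cases.
#'
#' @param n_train Training-set size, `1 <= n_train < cohort size`.
#' @param repetitions Number of random splits (default 25).
#' @param seed Master seed; each run uses an independent substream
#'   derived from `(seed, run_index)`.
#' @param stratified Preserve class proportions in the train set.
#' @param feature_set `"pv"` (all 10 features), `"p"` or `"v"` (the 5
#'   per-channel features).
#' @return A `split_spec` object.
#' @export
split_spec <- function(n_train, repetitions = 25L, seed = 0L,
                       stratified = TRUE, feature_set = c("pv", "p", "v")) {
  feature_set <- match.arg(feature_set)
  n_train <- as.integer(n_train)
  repetitions <- as.integer(repetitions)
  if (is.na(n_train) || n_train < 1L) {
    stop("`n_train` must be a positive integer", call. = FALSE)
  }
  if (is.na(repetitions) || repetitions < 1L) {
    stop("`repetitions` must be >= 1", call. = FALSE)
  }
  structure(
    list(
      n_train = n_train, repetitions = repetitions,
      seed = as.integer(seed), stratified = isTRUE(stratified),
      feature_set = feature_set
    ),
    class = "split_spec"
  )
}

# round half away from zero (tables render 89.25 -> 89.3, not banker's)
#' Round half-up to a fixed number of decimals
#'
#' Plain decimal rounding with halves away from zero, the convention of
#' printed results tables (in contrast to R's banker's rounding).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# independent RNG substream seed for one run, kept below 2^31
derive_run_seed <- function(seed, run_index) {
  as.integer((as.double(seed %% 1000003L) * 8191 +
                as.double(run_index) * 524287) %% 2147483629)
}

#' Draw one train/test split
#'
#' Partitions the sample ids into disjoint, exhaustive train and test
#' sets with `|train| = n_train`, using the substream derived from
#' `(spec$seed, run_index)` so individual runs are reproducible.
#' Stratified mode allocates `round(n_train * class share)` training
#' slots per class (half-up, clamped so both sets stay feasible).
#'
#' @param sample_ids Unique sample identifiers.
#' @param labels Class labels (+1/-1), parallel to `sample_ids`;
#'   required for stratified splits.
#' @param spec A [split_spec()].
#' @param run_index Run number (1-based).
#' @return List with character vectors `train` and `test`.
#' @export
make_split <- function(sample_ids, labels, spec, run_index = 1L) {
  if (anyDuplicated(sample_ids)) {
    stop("`sample_ids` must be unique", call. = FALSE)
  }
  n <- length(sample_ids)
  if (spec$n_train >= n) {
    stop("`n_train` (", spec$n_train, ") must be smaller than the cohort (",
         n, ")", call. = FALSE)
  }
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(derive_run_seed(spec$seed, run_index))
  if (spec$stratified) {
    stopifnot(length(labels) == n)
    pos <- sample_ids[labels == 1]
    neg <- sample_ids[labels == -1]
    n_pos_train <- round_half_up(spec$n_train * length(pos) / n, 0L)
    n_pos_train <- min(max(n_pos_train, spec$n_train - length(neg)),
                       length(pos), spec$n_train)
    n_neg_train <- spec$n_train - n_pos_train
    train <- c(
      sample(pos, n_pos_train),
      sample(neg, n_neg_train)
    )
  } else {
    train <- sample(sample_ids, spec$n_train)
  }
  list(train = train, test = setdiff(sample_ids, train))
}

#' Confusion-matrix metrics
#'
#' Melanoma (+1) is the positive class. Sensitivity is the true-positive
#' rate in percent, specificity the true-negative rate, accuracy the
#' overall fraction correct, and `error_rate = 1 - accuracy/100`. If a
#' class is absent from `truth`, the corresponding rate is `NA` with a
#' warning rather than a silent 0.
#'
#' @param predicted,truth Label vectors (+1/-1) of equal length.
#' @return A `metrics` list: `tp, fn, tn, fp, sensitivity, specificity,
#'   accuracy, error_rate`.
#' @export
#' @examples
#' compute_metrics(predicted = c(1, -1, -1), truth = c(1, 1, -1))
compute_metrics <- function(predicted, truth) {
  if (length(predicted) != length(truth) || length(truth) < 1L) {
    stop("`predicted` and `truth` must have equal positive length",
         call. = FALSE)
  }
  tp <- sum(predicted == 1 & truth == 1)
  fn <- sum(predicted == -1 & truth == 1)
  tn <- sum(predicted == -1 & truth == -1)
  fp <- sum(predicted == 1 & truth == -1)
  metrics_from_counts(tp, fn, tn, fp)
}

#' @rdname compute_metrics
#' @param tp,fn,tn,fp Confusion-matrix counts.
#' @export
metrics_from_counts <- function(tp, fn, tn, fp) {
  p <- tp + fn
  n <- tn + fp
  sens <- if (p > 0) 100 * tp / p else {
    warning("no positive cases in truth; sensitivity undefined")
    NA_real_
  }
  spec <- if (n > 0) 100 * tn / n else {
    warning("no negative cases in truth; specificity undefined")
    NA_real_
  }
  acc <- 100 * (tp + tn) / (p + n)
  structure(
    list(
      tp = tp, fn = fn, tn = tn, fp = fp,
      sensitivity = sens, specificity = spec, accuracy = acc,
      error_rate = 1 - acc / 100
    ),
    class = "metrics"
  )
}

#' @export
print.metrics <- function(x, ...) {
  cat(sprintf(
    "<metrics> tp %d fn %d tn %d fp %d | sens %.1f spec %.1f acc %.1f\n",
    x$tp, x$fn, x$tn, x$fp, x$sensitivity, x$specificity, x$accuracy
  ))
  invisible(x)
}

#' Average per-run metrics
#'
#' Arithmetic column means over runs, at full precision. Results tables
#' render these to one decimal (half-up, see [round_half_up()]).
#'
#' @param per_run Data frame with columns `sensitivity`, `specificity`,
#'   `accuracy` (such as `eval_report$per_run`), or a list of `metrics`.
#' @return Named list `sensitivity`, `specificity`, `accuracy`.
#' @export
aggregate_metrics <- function(per_run) {
  if (is.data.frame(per_run)) {
    df <- per_run
  } else if (is.list(per_run) && length(per_run) > 0L &&
             inherits(per_run[[1]], "metrics")) {
    df <- do.call(rbind, lapply(per_run, function(m) {
      as.data.frame(m[c("sensitivity", "specificity", "accuracy")])
    }))
  } else {
    stop("`per_run` must be a non-empty data frame or list of metrics",
         call. = FALSE)
  }
  if (nrow(df) < 1L) {
    stop("`per_run` must contain at least one run", call. = FALSE)
  }
  list(
    sensitivity = mean(df$sensitivity),
    specificity = mean(df$specificity),
    accuracy = mean(df$accuracy)
  )
}

#' Run a repeated random-split experiment
#'
#' For each repetition: draw a train/test split ([make_split()]),
#' restrict the feature table to the configured channel subset, train
#' the classifier, predict the test set, and compute confusion metrics.
#' The report carries every per-run row plus the averages; it is fully
#' reproducible from `(features, classifier_spec, split_spec)`.
#'
#' @param features Labelled feature table ([featurize_cohort()] /
#'   [read_features()]), both classes present.
#' @param clf_spec A [classifier_spec()].
#' @param splits A [split_spec()].
#' @return An `eval_report`: list with `per_run` (data frame of runs x
#'   confusion counts and rates), `averages`, and `config`.
#' @export
run_experiment <- function(features, clf_spec, splits) {
  stopifnot(inherits(clf_spec, "classifier_spec"),
            inherits(splits, "split_spec"))
  if (anyNA(features$label)) {
    stop("evaluation requires a fully labelled cohort", call. = FALSE)
  }
  cols <- feature_set_columns(splits$feature_set)
  keep <- c("sample_id", "label", cols)
  feats <- features[keep]
  per_run <- lapply(seq_len(splits$repetitions), function(run) {
    res <- tryCatch({
      sp <- make_split(feats$sample_id, feats$label, splits, run)
      train_df <- feats[feats$sample_id %in% sp$train, ]
      test_df <- feats[feats$sample_id %in% sp$test, ]
      model <- train_classifier(train_df, clf_spec)
      pred <- predict(model, test_df)
      compute_metrics(pred$label, test_df$label)
    }, error = function(e) {
      stop("run ", run, " failed: ", conditionMessage(e), call. = FALSE)
    })
    data.frame(
      run = run, tp = res$tp, fn = res$fn, tn = res$tn, fp = res$fp,
      sensitivity = res$sensitivity, specificity = res$specificity,
      accuracy = res$accuracy, error_rate = res$error_rate
    )
  })
  per_run <- do.call(rbind, per_run)
  rownames(per_run) <- NULL
  structure(
    list(
      per_run = per_run,
      averages = aggregate_metrics(per_run),
      config = list(classifier = clf_spec, splits = splits)
    ),
    class = "eval_report"
  )
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "Repeated random-split evaluation: %s, feature set %s, %d/%d split, %d runs%s\n",
    x$config$classifier$kind, x$config$splits$feature_set,
    x$config$splits$n_train,
    sum(x$per_run$tp[1], x$per_run$fn[1], x$per_run$tn[1], x$per_run$fp[1]),
    x$config$splits$repetitions,
    ifelse(x$config$splits$stratified, ", stratified", "")
  ))
  tab <- data.frame(
    Run = paste0("#", x$per_run$run),
    Sensitivity = round_half_up(x$per_run$sensitivity, 1L),
    Specificity = round_half_up(x$per_run$specificity, 1L),
    Accuracy = round_half_up(x$per_run$accuracy, 1L)
  )
  tab <- rbind(tab, data.frame(
    Run = "Average",
    Sensitivity = round_half_up(x$averages$sensitivity, 1L),
    Specificity = round_half_up(x$averages$specificity, 1L),
    Accuracy = round_half_up(x$averages$accuracy, 1L)
  ))
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Write an evaluation report as a results-table CSV
#'
#' One row per run plus an `Average` row, columns
#' `run,sensitivity,specificity,accuracy` rendered to one decimal
#' (half-up); a YAML sidecar `<path>.config.yml` records the full
#' configuration.
#'
#' @param report An `eval_report`.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  stopifnot(inherits(report, "eval_report"))
  tab <- data.frame(
    run = c(paste0("run_", report$per_run$run), "Average"),
    sensitivity = round_half_up(
      c(report$per_run$sensitivity, report$averages$sensitivity), 1L),
    specificity = round_half_up(
      c(report$per_run$specificity, report$averages$specificity), 1L),
    accuracy = round_half_up(
      c(report$per_run$accuracy, report$averages$accuracy), 1L)
  )
  utils::write.csv(tab, path, row.names = FALSE, quote = FALSE)
  cfg <- list(
    classifier = unclass(report$config$classifier),
    splits = unclass(report$config$splits)
  )
  yaml::write_yaml(cfg, paste0(path, ".config.yml"))
  invisible(path)
}
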