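#' Diagnose a subject from six scan files
#'
#' The end-to-end diagnosis path of the desktop workflow: load the six
#' scans, median-filter, normalize, compute the lesion-minus-normal
#' corrected images, extract the 10 features, and classify with a
#' trained model (the shipped configuration is naive Bayes on the
#' combined P+V features). Missing or unreadable scans abort with an
#' error naming the slot.
#'
#' @param p1,p2,p3,v1,v2,v3 Scan file paths (or `spectral_scan`
#'   objects): P/V polarization, lesion spots 1-2 and the normal spot.
#' @param model A `melaspec_model` trained on the full 10-feature set.
#' @param window Median-filter window.
#' @param sample_id Identifier for the report.
#' @param comment Free-text note carried into the result.
#' @param n_rows,n_cols Scan dimensions when reading from file.
#' @param verbose Log each pipeline stage via `message()`.
#' @return A `diagnosis` list: `sample_id`, `call` (`"melanoma"` or
#'   `"benign"`), `scores`, `model_kind`, `comment`.
#' @export
diagnose <- function(p1, p2, p3, v1, v2, v3, model,
                     window = c(3L, 3L), sample_id = "subject",
                     comment = "", n_rows = 32L, n_cols = 512L,
                     verbose = FALSE) {
  stopifnot(inherits(model, "melaspec_model"))
  if (!setequal(model$feature_names, FEATURE_COLUMNS)) {
    stop("diagnosis requires a model trained on the combined P+V feature set",
         call. = FALSE)
  }
  log_stage <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)
  inputs <- list(p1 = p1, p2 = p2, p3 = p3, v1 = v1, v2 = v2, v3 = v3)
  scans <- lapply(SCAN_SLOTS, function(slot) {
    s <- inputs[[slot]]
    if (inherits(s, "spectral_scan")) return(s)
    if (!is.character(s) || length(s) != 1L || !file.exists(s)) {
      stop("scan slot `", slot, "` is missing or unreadable: ",
           if (is.character(s)) s else class(s)[1], call. = FALSE)
    }
    meta <- slot_meta(slot)
    log_stage("loading ", slot, " from ", s)
    read_scan(s, n_rows = n_rows, n_cols = n_cols,
              polarization = meta$polarization, spot_role = meta$spot_role)
  })
  names(scans) <- SCAN_SLOTS
  sample <- sample_record(sample_id, scans, "unknown")
  log_stage("preprocessing and extracting features")
  fv <- build_feature_vector(sample, window)
  log_stage("classifying with ", model$spec$kind)
  pred <- predict(model, fv)
  structure(
    list(
      sample_id = sample_id,
      call = decode_label(pred$label),
      scores = c(melanoma = pred$score_melanoma, benign = pred$score_benign),
      model_kind = model$spec$kind,
      comment = comment
    ),
    class = "diagnosis"
  )
}

#' @export
print.diagnosis <- function(x, ...) {
  cat(sprintf(
    "Diagnosis for %s: %s (scores: melanoma %.3f, benign %.3f; model %s)\n",
    x$sample_id, toupper(x$call), x$scores[["melanoma"]],
    x$scores[["benign"]], x$model_kind
  ))
  if (nzchar(x$comment)) cat("Comment:", x$comment, "\n")
  invisible(x)
}

#' Default configuration for the one-command pipeline
#'
#' Defaults mirror the primary study conditions: a 19 melanoma / 168
#' benign cohort of 32 x 512 scans, a 3 x 3 median filter, naive Bayes
#' on the combined P+V features, and 25 stratified 60/127 splits.
#'
#' @return Nested list with sections `simulate`, `preprocess`, `train`,
#'   `evaluate`, `output`.
#' @export
default_pipeline_config <- function() {
  list(
    simulate = list(
      n_melanoma = 19L, n_benign = 168L, n_rows = 32L, n_cols = 512L,
      peak_row = 15L, effect_size = 1, noise_rate = 0.001,
      subject_shift_sd = 0.1, seed = 1L,
      write_scans = TRUE, layout = "f32"
    ),
    preprocess = list(window = 3L),
    train = list(classifier = "nb", seed = 0L),
    evaluate = list(
      n_train = 60L, repetitions = 25L, seed = 0L,
      stratified = TRUE, feature_set = "pv"
    ),
    output = list(directory = "melaspec_run")
  )
}

# merge user config over defaults, section by section
merge_config <- function(config) {
  base <- default_pipeline_config()
  for (section in names(base)) {
    for (key in names(config[[section]])) {
      if (!key %in% names(base[[section]])) {
        stop("unknown config key: ", section, "/", key, call. = FALSE)
      }
      base[[section]][[key]] <- config[[section]][[key]]
    }
  }
  extra <- setdiff(names(config), names(base))
  if (length(extra) > 0L) {
    stop("unknown config section(s): ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  base
}

#' Run the full pipeline from a single configuration
#'
#' Simulate a cohort, extract features, train a classifier and run the
#' repeated-split evaluation in one call. All artifacts land in the
#' output directory: `config.yml` (the resolved configuration),
#' `features.csv`, `model.yml`, `report.csv` (+ config sidecar), and
#' optionally the scan files plus `manifest.csv`. Re-running the same
#' configuration reproduces every artifact byte for byte.
#'
#' @param config Path to a YAML config file, or a nested list; any
#'   omitted key falls back to [default_pipeline_config()].
#' @param verbose Log stage progress.
#' @return List with `features`, `model`, `report`, and the resolved
#'   `config`, invisibly.
#' @export
run_full_pipeline <- function(config = list(), verbose = FALSE) {
  if (is.character(config) && length(config) == 1L) {
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_config(config)
  out_dir <- cfg$output$directory
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_stage <- function(...) if (verbose) message(format(Sys.time(), "%H:%M:%S "), ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage `", name, "` failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  yaml::write_yaml(cfg, file.path(out_dir, "config.yml"))

  log_stage("simulating cohort")
  cohort <- stage("simulate", {
    sim <- cfg$simulate
    spec <- cohort_spec(
      sim$n_melanoma, sim$n_benign, sim$n_rows, sim$n_cols, sim$peak_row,
      sim$effect_size, sim$noise_rate, sim$subject_shift_sd, sim$seed
    )
    generate_cohort(spec)
  })
  if (isTRUE(cfg$simulate$write_scans)) {
    log_stage("writing scans and manifest")
    stage("simulate", write_cohort(cohort, out_dir,
                                   layout = cfg$simulate$layout))
  }

  log_stage("extracting features")
  features <- stage("features",
                    featurize_cohort(cohort, window = cfg$preprocess$window))
  write_features(features, file.path(out_dir, "features.csv"))

  log_stage("training ", cfg$train$classifier, " on the full cohort")
  model <- stage("train", {
    clf <- classifier_spec(cfg$train$classifier, seed = cfg$train$seed)
    train_classifier(features, clf)
  })
  write_model(model, file.path(out_dir, "model.yml"))

  log_stage("running repeated-split evaluation")
  report <- stage("evaluate", {
    clf <- classifier_spec(cfg$train$classifier, seed = cfg$train$seed)
    sp <- split_spec(cfg$evaluate$n_train, cfg$evaluate$repetitions,
                     cfg$evaluate$seed, cfg$evaluate$stratified,
                     cfg$evaluate$feature_set)
    run_experiment(features, clf, sp)
  })
  write_report(report, file.path(out_dir, "report.csv"))

  invisible(list(features = features, model = model, report = report,
                 config = cfg))
}
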