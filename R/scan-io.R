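#' @useDynLib melaspec, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats dnorm runif rnorm rbinom median sd
#' @importFrom utils read.csv write.csv
NULL

POLARIZATIONS <- c("P", "V")
SPOT_ROLES <- c("lesion1", "lesion2", "normal")
SCAN_SLOTS <- c("p1", "p2", "p3", "v1", "v2", "v3")
FEATURE_COLUMNS <- c(
  "p_mean", "p_sd", "p_mad", "p_l1", "p_l2",
  "v_mean", "v_sd", "v_mad", "v_l1", "v_l2"
)
MANIFEST_COLUMNS <- c("sample_id", "label", SCAN_SLOTS)

#' Construct a spectral scan
#'
#' A spectral scan is one CCD exposure: a matrix of non-negative
#' intensities (rows index detector lines, columns index the spectral
#' axis; pixel (1, 1) is the first stored value), together with the
#' polarization channel of the probe (`"P"` parallel-polarized, `"V"`
#' cross-polarized) and the probed spot (`"lesion1"`/`"lesion2"` inside
#' the lesion, `"normal"` on nearby healthy skin).
#'
#' @param intensities Numeric matrix of finite, non-negative intensities.
#' @param polarization `"P"` or `"V"`.
#' @param spot_role `"lesion1"`, `"lesion2"` or `"normal"`.
#' @return A `spectral_scan` object.
#' @export
#' @examples
#' s <- spectral_scan(matrix(runif(32), 4, 8), "P", "lesion1")
#' dim(s)
spectral_scan <- function(intensities, polarization, spot_role) {
  if (!is.matrix(intensities) || !is.numeric(intensities)) {
    stop("`intensities` must be a numeric matrix", call. = FALSE)
  }
  if (anyNA(intensities) || any(!is.finite(intensities))) {
    stop("`intensities` must be finite (no NA/NaN/Inf)", call. = FALSE)
  }
  if (any(intensities < 0)) {
    stop("`intensities` must be non-negative", call. = FALSE)
  }
  polarization <- match.arg(polarization, POLARIZATIONS)
  spot_role <- match.arg(spot_role, SPOT_ROLES)
  structure(
    list(
      intensities = unname(intensities),
      polarization = polarization,
      spot_role = spot_role
    ),
    class = "spectral_scan"
  )
}

#' @export
dim.spectral_scan <- function(x) dim(x$intensities)

#' @export
as.matrix.spectral_scan <- function(x, ...) x$intensities

#' @export
print.spectral_scan <- function(x, ...) {
  d <- dim(x$intensities)
  cat(sprintf(
    "<spectral_scan> %d x %d, polarization %s, spot %s, range [%.4g, %.4g]\n",
    d[1], d[2], x$polarization, x$spot_role,
    min(x$intensities), max(x$intensities)
  ))
  invisible(x)
}

# slot name ("p1".."v3") -> (polarization, spot_role)
slot_meta <- function(slot) {
  pol <- if (substr(slot, 1, 1) == "p") "P" else "V"
  role <- c("lesion1", "lesion2", "normal")[as.integer(substr(slot, 2, 2))]
  list(polarization = pol, spot_role = role)
}

#' Construct a six-scan sample record
#'
#' One subject-sample: six spectral scans (two lesion spots and one
#' normal-skin spot, each in both polarization channels) and a class
#' label. Labels are encoded as +1 for melanoma (the positive, cancer
#' class), -1 for benign, and `NA` for an unlabelled sample awaiting
#' diagnosis.
#'
#' @param sample_id Character scalar, unique within a cohort.
#' @param scans Named list with entries `p1, p2, p3, v1, v2, v3`, each a
#'   `spectral_scan` (or bare matrix, coerced using the slot's metadata).
#'   All six must share the same dimensions.
#' @param label `"melanoma"`, `"benign"`, `"unknown"`, or the numeric
#'   codes `+1`, `-1`, `NA`.
#' @return A `sample_record` object.
#' @export
sample_record <- function(sample_id, scans, label = "unknown") {
  if (!is.character(sample_id) || length(sample_id) != 1L || !nzchar(sample_id)) {
    stop("`sample_id` must be a non-empty string", call. = FALSE)
  }
  missing_slots <- setdiff(SCAN_SLOTS, names(scans))
  if (length(missing_slots) > 0L) {
    stop(
      "missing scan slot(s): ", paste(missing_slots, collapse = ", "),
      call. = FALSE
    )
  }
  scans <- lapply(SCAN_SLOTS, function(slot) {
    s <- scans[[slot]]
    if (is.matrix(s)) {
      meta <- slot_meta(slot)
      s <- spectral_scan(s, meta$polarization, meta$spot_role)
    }
    if (!inherits(s, "spectral_scan")) {
      stop("scan slot `", slot, "` is not a spectral_scan", call. = FALSE)
    }
    s
  })
  names(scans) <- SCAN_SLOTS
  dims <- vapply(scans, function(s) dim(s$intensities), integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1])) {
    stop("all six scans must share the same dimensions", call. = FALSE)
  }
  structure(
    list(sample_id = sample_id, scans = scans, label = encode_label(label)),
    class = "sample_record"
  )
}

#' @export
print.sample_record <- function(x, ...) {
  d <- dim(x$scans$p1$intensities)
  cat(sprintf(
    "<sample_record> %s: six %d x %d scans, label %s\n",
    x$sample_id, d[1], d[2], decode_label(x$label)
  ))
  invisible(x)
}

#' Convert between text labels and the +1/-1 class coding
#'
#' Melanoma is the positive class (+1), benign the negative class (-1);
#' an unknown label (a sample awaiting diagnosis) is `NA`.
#'
#' @param label Character (`"melanoma"`, `"benign"`, `"unknown"`) or
#'   numeric (+1, -1, NA) vector.
#' @return `encode_label()` returns the numeric coding; `decode_label()`
#'   the character form.
#' @export
encode_label <- function(label) {
  if (is.numeric(label)) {
    bad <- !is.na(label) & !(label %in% c(1, -1))
    if (any(bad)) {
      stop("numeric labels must be +1, -1 or NA", call. = FALSE)
    }
    return(as.numeric(label))
  }
  out <- rep(NA_real_, length(label))
  out[label == "melanoma"] <- 1
  out[label == "benign"] <- -1
  bad <- !(label %in% c("melanoma", "benign", "unknown"))
  if (any(bad)) {
    stop(
      "unrecognized label(s): ", paste(unique(label[bad]), collapse = ", "),
      call. = FALSE
    )
  }
  out
}

#' @rdname encode_label
#' @export
decode_label <- function(label) {
  out <- rep("unknown", length(label))
  out[!is.na(label) & label == 1] <- "melanoma"
  out[!is.na(label) & label == -1] <- "benign"
  out
}

#' Read a spectral scan from disk
#'
#' Two portable layouts are supported. `"f32"` is a headerless raw file
#' of little-endian 32-bit floats in row-major pixel order (pixel (1, 1)
#' first), exactly `n_rows * n_cols` values. `"text"` is a plain CSV
#' matrix: `n_rows` lines of `n_cols` comma-separated values.
#'
#' @param path File path.
#' @param layout `"auto"` (by file extension: `.f32` raw, anything else
#'   text), `"f32"`, or `"text"`.
#' @param n_rows,n_cols Expected dimensions (defaults 32 x 512, the CCD
#'   frame size).
#' @param polarization,spot_role Scan metadata to attach.
#' @return A [spectral_scan()].
#' @export
read_scan <- function(path, layout = c("auto", "f32", "text"),
                      n_rows = 32L, n_cols = 512L,
                      polarization = "P", spot_role = "lesion1") {
  layout <- match.arg(layout)
  if (!file.exists(path)) {
    stop("scan file not found: ", path, call. = FALSE)
  }
  if (layout == "auto") {
    layout <- if (grepl("\\.f32$", path, ignore.case = TRUE)) "f32" else "text"
  }
  n_px <- as.integer(n_rows) * as.integer(n_cols)
  if (layout == "f32") {
    n_bytes <- file.info(path)$size
    if (n_bytes != 4L * n_px) {
      stop(sprintf(
        "raw scan %s has %d bytes; expected %d (= %d x %d float32 values)",
        path, n_bytes, 4L * n_px, n_rows, n_cols
      ), call. = FALSE)
    }
    con <- file(path, "rb")
    on.exit(close(con))
    vals <- readBin(con, what = "numeric", n = n_px, size = 4L,
                    endian = "little")
  } else {
    rows <- tryCatch(
      utils::read.csv(path, header = FALSE, colClasses = "numeric"),
      error = function(e) {
        stop("cannot parse text scan ", path, ": ", conditionMessage(e),
             call. = FALSE)
      }
    )
    if (nrow(rows) != n_rows || ncol(rows) != n_cols) {
      stop(sprintf(
        "text scan %s is %d x %d; expected %d x %d",
        path, nrow(rows), ncol(rows), n_rows, n_cols
      ), call. = FALSE)
    }
    vals <- as.numeric(t(as.matrix(rows)))
  }
  m <- matrix(vals, nrow = n_rows, ncol = n_cols, byrow = TRUE)
  spectral_scan(m, polarization, spot_role)
}

#' Write a spectral scan to disk
#'
#' @inheritParams read_scan
#' @param scan A [spectral_scan()] or numeric matrix.
#' @return Invisibly, `path`.
#' @export
write_scan <- function(scan, path, layout = c("auto", "f32", "text")) {
  layout <- match.arg(layout)
  m <- if (inherits(scan, "spectral_scan")) scan$intensities else scan
  if (layout == "auto") {
    layout <- if (grepl("\\.f32$", path, ignore.case = TRUE)) "f32" else "text"
  }
  if (layout == "f32") {
    con <- file(path, "wb")
    on.exit(close(con))
    # row-major order: transpose since R stores column-major
    writeBin(as.numeric(t(m)), con, size = 4L, endian = "little")
  } else {
    utils::write.table(m, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  }
  invisible(path)
}

#' Read a cohort manifest
#'
#' The manifest is a CSV with header
#' `sample_id,label,p1,p2,p3,v1,v2,v3`; each row names a sample, its
#' label (`melanoma`/`benign`/`unknown`) and the six scan files
#' (relative paths are resolved against the manifest's directory).
#' Records are returned in manifest row order.
#'
#' @param path Manifest CSV path.
#' @param n_rows,n_cols Expected scan dimensions.
#' @return List of [sample_record()]s.
#' @export
read_manifest <- function(path, n_rows = 32L, n_cols = 512L) {
  if (!file.exists(path)) {
    stop("manifest not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = "character")
  missing_cols <- setdiff(MANIFEST_COLUMNS, names(df))
  if (length(missing_cols) > 0L) {
    stop(
      "manifest is missing column(s): ", paste(missing_cols, collapse = ", "),
      call. = FALSE
    )
  }
  if (anyDuplicated(df$sample_id)) {
    dup <- unique(df$sample_id[duplicated(df$sample_id)])
    stop("duplicate sample_id(s) in manifest: ", paste(dup, collapse = ", "),
         call. = FALSE)
  }
  base_dir <- dirname(path)
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    scans <- lapply(SCAN_SLOTS, function(slot) {
      p <- row[[slot]]
      if (!file.exists(p)) {
        p2 <- file.path(base_dir, p)
        if (!file.exists(p2)) {
          stop("scan file for sample ", row$sample_id, " slot ", slot,
               " not found: ", p, call. = FALSE)
        }
        p <- p2
      }
      meta <- slot_meta(slot)
      read_scan(p, n_rows = n_rows, n_cols = n_cols,
                polarization = meta$polarization, spot_role = meta$spot_role)
    })
    names(scans) <- SCAN_SLOTS
    sample_record(row$sample_id, scans, row$label)
  })
}

#' Read or write a feature table
#'
#' Feature tables are CSVs with header
#' `sample_id,label,p_mean,p_sd,p_mad,p_l1,p_l2,v_mean,v_sd,v_mad,v_l1,v_l2`.
#' In memory the label column is the +1/-1/NA coding; on disk it is
#' `melanoma`/`benign`/`unknown`.
#'
#' @param features Data frame as returned by [featurize_cohort()].
#' @param path CSV path.
#' @return `read_features()` the data frame; `write_features()` the path,
#'   invisibly.
#' @export
write_features <- function(features, path) {
  stopifnot(is.data.frame(features))
  out <- features
  out$label <- decode_label(out$label)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  if (!file.exists(path)) {
    stop("feature table not found: ", path, call. = FALSE)
  }
  df <- utils::read.csv(path, colClasses = c(
    sample_id = "character", label = "character"
  ))
  missing_cols <- setdiff(c("sample_id", "label", FEATURE_COLUMNS), names(df))
  if (length(missing_cols) > 0L) {
    stop("feature table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  df$label <- encode_label(df$label)
  df
}

#' Save or load a trained classifier
#'
#' Models are stored as self-describing YAML: classifier kind, the full
#' [classifier_spec()], and all fitted parameters (Gaussian moments and
#' priors for naive Bayes, the memorized training set for k-NN, weight
#' matrices and scaling ranges for the neural network).
#'
#' @param model A `melaspec_model` from [train_classifier()].
#' @param path File path.
#' @return `read_model()` the model; `write_model()` the path, invisibly.
#' @export
write_model <- function(model, path) {
  stopifnot(inherits(model, "melaspec_model"))
  ser <- model
  ser$spec <- unclass(ser$spec)
  # matrices -> lists of rows so YAML stays human-readable and lossless
  ser$parameters <- rapply(ser$parameters, function(x) {
    if (is.matrix(x)) apply(x, 1, as.numeric, simplify = FALSE) else x
  }, how = "replace")
  ser$.matrix_fields <- names(Filter(is.matrix, model$parameters))
  yaml::write_yaml(ser, path, precision = 17L)
  invisible(path)
}

#' @rdname write_model
#' @export
read_model <- function(path) {
  if (!file.exists(path)) {
    stop("model file not found: ", path, call. = FALSE)
  }
  ser <- yaml::read_yaml(path)
  for (fld in ser$.matrix_fields) {
    ser$parameters[[fld]] <- do.call(rbind, lapply(ser$parameters[[fld]],
                                                   as.numeric))
  }
  ser$.matrix_fields <- NULL
  ser$spec <- structure(ser$spec, class = "classifier_spec")
  if (!is.null(ser$parameters$train_labels)) {
    ser$parameters$train_labels <- as.numeric(ser$parameters$train_labels)
  }
  if (!is.null(ser$scaling)) {
    ser$scaling <- lapply(ser$scaling, unlist)
  }
  for (fld in c("priors", "precision")) {
    if (!is.null(ser$parameters[[fld]])) {
      ser$parameters[[fld]] <- as.numeric(unlist(ser$parameters[[fld]]))
    }
  }
  structure(ser, class = "melaspec_model")
}
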