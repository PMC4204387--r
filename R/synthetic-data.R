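#' Specify a synthetic spectroscopic cohort
#'
#' Describes a cohort of labelled six-scan samples emulating the
#' clinical acquisition: every scan shows a smooth baseline surface — a
#' bright detector line at `peak_row` whose intensity tapers towards the
#' frame edges, modulated by a smooth spectral envelope along the
#' columns — scaled by a per-subject multiplicative shift shared by all
#' six scans of a sample. Lesion spots add a class effect on top:
#' benign lesions a small uniform lift (normalized pixel values
#' concentrate in `[0.2, 0.4]`), melanoma lesions an additional broad,
#' spatially varying lift scaled by `effect_size` (normalized values
#' spread over `[0, 1]` with heavy mass at high intensities). Isolated
#' salt-and-pepper pixels are injected at rate `noise_rate` — the noise
#' type the median-filter stage removes.
#'
#' @param n_melanoma,n_benign Sample counts per class (both >= 0, at
#'   least one sample in total). The clinical cohort the defaults of the
#'   downstream evaluation assume is 19 melanoma / 168 benign.
#' @param n_rows,n_cols Scan dimensions; default 32 x 512 (the CCD
#'   frame).
#' @param peak_row 1-based row of the bright detector line (default 15).
#' @param effect_size Non-negative scaling of the melanoma-vs-benign
#'   distributional shift. 0 removes all class signal; 1 (default) gives
#'   well-separated classes.
#' @param noise_rate Per-pixel impulse-noise probability in `[0, 1]`.
#' @param subject_shift_sd Standard deviation of the per-subject
#'   log-normal multiplicative baseline shift.
#' @param seed Integer seed; the same spec (including seed) always
#'   yields a bit-identical cohort.
#' @return A `cohort_spec` object.
#' @export
cohort_spec <- function(n_melanoma, n_benign, n_rows = 32L, n_cols = 512L,
                        peak_row = 15L, effect_size = 1, noise_rate = 0.001,
                        subject_shift_sd = 0.1, seed = 1L) {
  check_count <- function(x, name, min = 0L) {
    if (length(x) != 1L || is.na(x) || x != as.integer(x) || x < min) {
      stop("invalid `", name, "`: must be an integer >= ", min, call. = FALSE)
    }
    as.integer(x)
  }
  n_melanoma <- check_count(n_melanoma, "n_melanoma")
  n_benign <- check_count(n_benign, "n_benign")
  if (n_melanoma + n_benign < 1L) {
    stop("invalid `n_melanoma`/`n_benign`: cohort must have >= 1 sample",
         call. = FALSE)
  }
  n_rows <- check_count(n_rows, "n_rows", 2L)
  n_cols <- check_count(n_cols, "n_cols", 2L)
  peak_row <- check_count(peak_row, "peak_row", 1L)
  if (peak_row > n_rows) {
    stop("invalid `peak_row`: must be between 1 and n_rows", call. = FALSE)
  }
  if (length(effect_size) != 1L || is.na(effect_size) || effect_size < 0) {
    stop("invalid `effect_size`: must be a non-negative number",
         call. = FALSE)
  }
  if (length(noise_rate) != 1L || is.na(noise_rate) ||
      noise_rate < 0 || noise_rate > 1) {
    stop("invalid `noise_rate`: must be in [0, 1]", call. = FALSE)
  }
  if (length(subject_shift_sd) != 1L || is.na(subject_shift_sd) ||
      subject_shift_sd < 0) {
    stop("invalid `subject_shift_sd`: must be a non-negative number",
         call. = FALSE)
  }
  seed <- check_count(seed, "seed", 0L)
  structure(
    list(
      n_melanoma = n_melanoma, n_benign = n_benign,
      n_rows = n_rows, n_cols = n_cols, peak_row = peak_row,
      effect_size = as.numeric(effect_size),
      noise_rate = as.numeric(noise_rate),
      subject_shift_sd = as.numeric(subject_shift_sd),
      seed = seed
    ),
    class = "cohort_spec"
  )
}

#' @export
print.cohort_spec <- function(x, ...) {
  cat(sprintf(
    paste0(
      "<cohort_spec> %d melanoma + %d benign, %d x %d scans, peak row %d,\n",
      "  effect_size %g, noise_rate %g, subject_shift_sd %g, seed %d\n"
    ),
    x$n_melanoma, x$n_benign, x$n_rows, x$n_cols, x$peak_row,
    x$effect_size, x$noise_rate, x$subject_shift_sd, x$seed
  ))
  invisible(x)
}

# Smooth zero-centred random surface: low-frequency separable sinusoid
# modes with random frequencies and phases (low frequency so the median
# filter leaves it essentially unchanged). Two normalizations:
# "rms" fixes the root-mean-square amplitude to 1 (deterministic noise
# power per image, so image summary statistics vary smoothly and nearly
# normally across images); "max" bounds the surface in [-1, 1] (used
# where positivity of derived quantities must hold).
smooth_surface <- function(n_rows, n_cols, n_modes = 6L,
                           normalize = c("rms", "max")) {
  normalize <- match.arg(normalize)
  r <- seq_len(n_rows) / n_rows
  c <- seq_len(n_cols) / n_cols
  g <- matrix(0, n_rows, n_cols)
  for (m in seq_len(n_modes)) {
    fr <- sample(1:2, 1L)
    fc <- sample(1:3, 1L)
    a <- runif(1L, 0.3, 1)
    g <- g + a * outer(
      sin(2 * pi * fr * r + runif(1L, 0, 2 * pi)),
      sin(2 * pi * fc * c + runif(1L, 0, 2 * pi))
    )
  }
  if (normalize == "rms") {
    g / sqrt(mean(g^2))
  } else {
    g / max(abs(g))
  }
}

# Deterministic row profile: dark frame edges, bulk tissue level, and
# the bright detector line at peak_row.
row_profile <- function(n_rows, peak_row) {
  i <- seq_len(n_rows)
  edge_dist <- pmin(i - 1L, n_rows - i)
  edge <- 1 - exp(-edge_dist / 1.2)
  peak <- exp(-(i - peak_row)^2 / (2 * 1.5^2))
  0.02 + 0.28 * edge + 0.70 * peak
}

# Deterministic spectral envelope along the columns, in [0.85, 1].
col_profile <- function(n_cols) {
  j <- seq_len(n_cols) / n_cols
  0.85 + 0.15 * exp(-(j - 0.45)^2 / (2 * 0.35^2))
}

# One scan on the generator's internal positive scale.
# kind: "normal" (baseline only), "benign" or "melanoma" lesion spot.
simulate_scan <- function(spec, kind, subject_scale) {
  level <- row_profile(spec$n_rows, spec$peak_row)
  envelope <- col_profile(spec$n_cols)
  base <- outer(level, envelope) *
    (1 + 0.04 * smooth_surface(spec$n_rows, spec$n_cols))
  # lesion effects vanish at the dark frame edges, like real signal
  edge <- 1 - exp(-pmin(seq_len(spec$n_rows) - 1L,
                        spec$n_rows - seq_len(spec$n_rows)) / 1.2)
  vals <- base
  if (kind %in% c("benign", "melanoma")) {
    u_b <- (1 + smooth_surface(spec$n_rows, spec$n_cols,
                               normalize = "max")) / 2
    vals <- vals + edge * (0.02 + 0.02 * u_b)
  }
  if (kind == "melanoma" && spec$effect_size > 0) {
    u_m <- (1 + smooth_surface(spec$n_rows, spec$n_cols,
                               normalize = "max")) / 2
    vals <- vals + spec$effect_size * edge * (0.25 + 0.30 * u_m)
  }
  if (spec$noise_rate > 0) {
    hit <- which(runif(length(vals)) < spec$noise_rate)
    if (length(hit) > 0L) {
      salt <- runif(length(hit)) < 0.5
      vals[hit[salt]] <- max(vals) * 1.3
      vals[hit[!salt]] <- 0
    }
  }
  # arbitrary positive acquisition scale (CCD counts); min-max
  # normalization downstream removes it
  1000 * subject_scale * vals
}

#' Generate a synthetic labelled cohort
#'
#' Draws `n_melanoma + n_benign` six-scan samples according to a
#' [cohort_spec()]. Within each sample the normal-spot scans (`p3`,
#' `v3`) carry the subject baseline only; the lesion-spot scans add the
#' class effect. All six scans share the subject's multiplicative
#' baseline shift, which is exactly what the lesion-minus-normal
#' correction is designed to cancel.
#'
#' @param spec A [cohort_spec()].
#' @return List of [sample_record()]s: melanoma samples first
#'   (`mel_001`, ...), then benign (`ben_001`, ...).
#' @export
#' @examples
#' cohort <- generate_cohort(cohort_spec(2, 3, n_rows = 16, n_cols = 64,
#'                                       peak_row = 8, seed = 42))
#' length(cohort)
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ids <- c(
    sprintf("mel_%03d", seq_len(spec$n_melanoma)),
    sprintf("ben_%03d", seq_len(spec$n_benign))
  )
  labels <- c(rep("melanoma", spec$n_melanoma), rep("benign", spec$n_benign))
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)
  lapply(seq_along(ids), function(s) {
    subject_scale <- exp(rnorm(1L, 0, spec$subject_shift_sd))
    lesion_kind <- if (labels[s] == "melanoma") "melanoma" else "benign"
    scans <- lapply(SCAN_SLOTS, function(slot) {
      meta <- slot_meta(slot)
      kind <- if (meta$spot_role == "normal") "normal" else lesion_kind
      spectral_scan(simulate_scan(spec, kind, subject_scale),
                    meta$polarization, meta$spot_role)
    })
    names(scans) <- SCAN_SLOTS
    sample_record(ids[s], scans, labels[s])
  })
}

#' Write a cohort to disk
#'
#' Writes each scan as a file (raw `.f32` or text `.csv` layout, see
#' [write_scan()]) plus a manifest CSV with header
#' `sample_id,label,p1,p2,p3,v1,v2,v3` referencing the six files per
#' sample. An empty cohort yields a manifest with a header only.
#'
#' @param cohort List of [sample_record()]s.
#' @param directory Output directory (created if needed).
#' @param layout `"f32"` or `"text"`.
#' @return The manifest data frame, invisibly; the manifest file is
#'   `<directory>/manifest.csv`.
#' @export
write_cohort <- function(cohort, directory, layout = c("f32", "text")) {
  layout <- match.arg(layout)
  ext <- if (layout == "f32") "f32" else "csv"
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(directory)) {
    stop("cannot create output directory: ", directory, call. = FALSE)
  }
  rows <- lapply(cohort, function(sample) {
    paths <- vapply(SCAN_SLOTS, function(slot) {
      fname <- sprintf("%s_%s.%s", sample$sample_id, slot, ext)
      write_scan(sample$scans[[slot]], file.path(directory, fname),
                 layout = layout)
      fname
    }, character(1))
    df <- data.frame(
      sample_id = sample$sample_id,
      label = decode_label(sample$label),
      stringsAsFactors = FALSE
    )
    df[SCAN_SLOTS] <- as.list(paths)
    df
  })
  manifest <- if (length(rows) > 0L) {
    do.call(rbind, rows)
  } else {
    df <- data.frame(sample_id = character(), label = character(),
                     stringsAsFactors = FALSE)
    df[SCAN_SLOTS] <- replicate(6, character(), simplify = FALSE)
    df
  }
  rownames(manifest) <- NULL
  utils::write.csv(manifest, file.path(directory, "manifest.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(manifest)
}
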