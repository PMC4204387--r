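#' Median filter a scan
#'
#' Each output pixel is the median of the `window[1] x window[2]`
#' neighbourhood centred on it; image borders are handled by reflection
#' padding (the edge pixel is mirrored). With odd window extents the
#' output values are always a subset of the input values, which is why
#' the median filter is the denoiser of choice for the isolated
#' salt-and-pepper pixels a CCD picks up during acquisition.
#'
#' @param x A [spectral_scan()] or numeric matrix.
#' @param window Odd positive window extents, `c(rows, cols)`; a single
#'   number is recycled to both axes. Default `c(3, 3)`.
#' @return Same type as `x`, filtered, dimensions unchanged.
#' @export
#' @examples
#' m <- matrix(0, 5, 5); m[3, 3] <- 9
#' median_filter(m)            # the isolated spike is removed
median_filter <- function(x, window = c(3L, 3L)) {
  if (length(window) == 1L) window <- rep(window, 2L)
  window <- as.integer(window)
  if (length(window) != 2L || any(is.na(window)) || any(window < 1L) ||
      any(window %% 2L == 0L)) {
    stop("`window` extents must be odd positive integers", call. = FALSE)
  }
  m <- if (inherits(x, "spectral_scan")) x$intensities else x
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("`x` must be a numeric matrix or spectral_scan", call. = FALSE)
  }
  if (any(window > dim(m))) {
    stop("`window` must not exceed the image dimensions", call. = FALSE)
  }
  out <- median_filter_cpp(m, window[1L], window[2L])
  if (inherits(x, "spectral_scan")) {
    spectral_scan(out, x$polarization, x$spot_role)
  } else {
    out
  }
}

#' Min-max normalize a scan to [0, 1]
#'
#' Rescales intensities so the image minimum maps to exactly 0 and the
#' maximum to exactly 1: `(I - min) / (max - min)`. Each image is
#' normalized against its own extremes, making the result invariant to
#' positive affine transforms of the raw counts (gain and offset of the
#' detector, and any per-subject multiplicative baseline).
#'
#' A constant image is rejected: the rescaling is undefined there, and a
#' flat CCD frame indicates an acquisition failure.
#'
#' @param x A [spectral_scan()] or numeric matrix with at least two
#'   distinct values.
#' @return A `normalized_scan`: matrix of values in `[0, 1]` plus the
#'   source scan's polarization/spot metadata (or a bare matrix when `x`
#'   is a matrix).
#' @export
#' @examples
#' minmax_normalize(matrix(c(1, 2, 3, 5), 2, 2))
minmax_normalize <- function(x) {
  m <- if (inherits(x, "spectral_scan")) x$intensities else x
  if (!is.matrix(m) || !is.numeric(m)) {
    stop("`x` must be a numeric matrix or spectral_scan", call. = FALSE)
  }
  lo <- min(m)
  hi <- max(m)
  if (hi == lo) {
    stop("cannot min-max normalize a constant image (max == min)",
         call. = FALSE)
  }
  out <- (m - lo) / (hi - lo)
  if (inherits(x, "spectral_scan")) {
    structure(
      list(
        intensities = out,
        polarization = x$polarization,
        spot_role = x$spot_role
      ),
      class = "normalized_scan"
    )
  } else {
    out
  }
}

#' @export
as.matrix.normalized_scan <- function(x, ...) x$intensities

#' @export
dim.normalized_scan <- function(x) dim(x$intensities)

#' Lesion-minus-normal corrected intensity
#'
#' The per-pixel corrected intensity averages the two normalized lesion
#' scans and subtracts the normalized normal-skin scan:
#' `(s1 + s2) / 2 - s3`. Subject-level baseline structure common to all
#' three scans (skin colour, age, detector response) cancels, leaving the
#' lesion-specific signal. Values are signed and lie in `[-1, 1]`;
#' negative values are preserved.
#'
#' @param s1,s2 Normalized lesion-spot scans (`normalized_scan` or
#'   matrix in `[0, 1]`).
#' @param s3 Normalized normal-spot scan.
#' @param sample_id Optional identifier carried on the result.
#' @return A `corrected_image`: signed matrix plus polarization metadata
#'   (or a bare matrix when inputs are matrices).
#' @export
corrected_intensity <- function(s1, s2, s3, sample_id = NA_character_) {
  scans <- list(s1, s2, s3)
  is_scan <- vapply(scans, inherits, logical(1), "normalized_scan")
  mats <- lapply(scans, function(s) if (inherits(s, "normalized_scan")) s$intensities else s)
  dims <- lapply(mats, dim)
  if (is.null(dims[[1]]) ||
      !identical(dims[[1]], dims[[2]]) || !identical(dims[[1]], dims[[3]])) {
    stop("the three scans must be matrices of identical dimensions",
         call. = FALSE)
  }
  if (any(is_scan)) {
    pols <- unique(vapply(scans[is_scan], function(s) s$polarization,
                          character(1)))
    if (length(pols) > 1L) {
      stop("scans mix polarizations: ", paste(pols, collapse = ", "),
           call. = FALSE)
    }
    pol <- pols
  } else {
    pol <- NA_character_
  }
  vals <- (mats[[1]] + mats[[2]]) / 2 - mats[[3]]
  if (any(is_scan)) {
    structure(
      list(values = vals, polarization = pol, sample_id = sample_id),
      class = "corrected_image"
    )
  } else {
    vals
  }
}

#' @export
as.matrix.corrected_image <- function(x, ...) x$values

#' @export
dim.corrected_image <- function(x) dim(x$values)

#' @export
print.corrected_image <- function(x, ...) {
  cat(sprintf(
    "<corrected_image> %s polarization %s, range [%.4g, %.4g]\n",
    ifelse(is.na(x$sample_id), "", x$sample_id), x$polarization,
    min(x$values), max(x$values)
  ))
  invisible(x)
}

#' Preprocess a six-scan sample into corrected P and V images
#'
#' Runs the full preprocessing chain on every scan of a sample — median
#' filtering first, then min-max normalization (this order matters: the
#' filter must see the raw counts so that impulse noise cannot pin the
#' normalization extremes) — and computes the lesion-minus-normal
#' corrected image separately for the P channel (p1, p2, p3) and the V
#' channel (v1, v2, v3).
#'
#' @param sample A [sample_record()].
#' @param window Median-filter window, as in [median_filter()].
#' @return List with elements `P` and `V`, each a `corrected_image`.
#' @export
preprocess_sample <- function(sample, window = c(3L, 3L)) {
  stopifnot(inherits(sample, "sample_record"))
  norm <- lapply(SCAN_SLOTS, function(slot) {
    tryCatch(
      minmax_normalize(median_filter(sample$scans[[slot]], window)),
      error = function(e) {
        stop("preprocessing failed for sample ", sample$sample_id,
             " scan ", slot, ": ", conditionMessage(e), call. = FALSE)
      }
    )
  })
  names(norm) <- SCAN_SLOTS
  list(
    P = corrected_intensity(norm$p1, norm$p2, norm$p3,
                            sample_id = sample$sample_id),
    V = corrected_intensity(norm$v1, norm$v2, norm$v3,
                            sample_id = sample$sample_id)
  )
}
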