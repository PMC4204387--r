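#' Reference per-run naive Bayes evaluation results
#'
#' The published per-run sensitivity/specificity/accuracy (in percent)
#' of the naive Bayes classifier on the combined P+V features over 25
#' stratified 60/127 random splits of the original 187-sample clinical
#' cohort (19 melanoma, 168 benign). Shipped as a plain-text fixture
#' for regression-testing the aggregation arithmetic: feeding these 25
#' rows to [aggregate_metrics()] must reproduce the published average
#' row (88.6 / 89.3 / 89.2 at one-decimal half-up rounding).
#'
#' Every sensitivity in the table is an integer multiple of 100/13 —
#' the fingerprint of a constant 13 melanoma cases per test set, i.e.
#' of stratified splitting (which is why [split_spec()] stratifies by
#' default).
#'
#' @return Data frame with columns `run`, `sensitivity`, `specificity`,
#'   `accuracy` (25 rows).
#' @export
#' @examples
#' runs <- reference_nb_runs()
#' sapply(aggregate_metrics(runs), round_half_up, digits = 1)
reference_nb_runs <- function() {
  path <- system.file("extdata", "nb_pv_reference_runs.csv",
                      package = "melaspec", mustWork = TRUE)
  utils::read.csv(path)
}
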