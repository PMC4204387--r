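Package: melaspec
Title: Melanoma Classification from Polarized Light Spectroscopy Scans
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Analysis pipeline for diagnosing melanoma from paired
    polarized (P) and unpolarized (V) spectroscopic skin scans. Provides
    preprocessing (median filtering, min-max normalization, lesion-minus-
    normal intensity correction), extraction of ten statistical intensity
    features, from-scratch naive Bayes, k-nearest-neighbour and
    back-propagation neural-network classifiers, repeated random-split
    evaluation with sensitivity/specificity/accuracy reporting, and a
    synthetic-cohort simulator for end-to-end testing without clinical
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    e1071,
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
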