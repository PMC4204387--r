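fake_ids <- function(n) sprintf("id%03d", seq_len(n))

cohort_labels <- function(n_pos, n_neg) c(rep(1, n_pos), rep(-1, n_neg))

test_that("splits have the study sizes and partition the cohort", {
  ids <- fake_ids(187)
  labels <- cohort_labels(19, 168)
  sp <- make_split(ids, labels, split_spec(60), run_index = 1L)
  expect_length(sp$train, 60L)
  expect_length(sp$test, 127L)
  expect_length(intersect(sp$train, sp$test), 0L)
  expect_setequal(c(sp$train, sp$test), ids)
  sp30 <- make_split(ids, labels, split_spec(30), run_index = 1L)
  expect_length(sp30$train, 30L)
  expect_length(sp30$test, 157L)
  expect_error(make_split(ids, labels, split_spec(187)), "smaller")
  expect_error(make_split(c("a", "a"), c(1, -1), split_spec(1)), "unique")
})

test_that("stratified 60/127 splits leave exactly 13 melanoma in the test set", {
  ids <- fake_ids(187)
  labels <- cohort_labels(19, 168)
  spec <- split_spec(60, stratified = TRUE, seed = 8L)
  for (run in 1:25) {
    sp <- make_split(ids, labels, spec, run)
    test_pos <- sum(labels[match(sp$test, ids)] == 1)
    expect_identical(test_pos, 13L)
    expect_identical(sum(labels[match(sp$train, ids)] == 1), 6L)
  }
  # 30/157 variant: 3 melanoma in train
  sp <- make_split(ids, labels, split_spec(30, stratified = TRUE), 1L)
  expect_identical(sum(labels[match(sp$train, ids)] == 1), 3L)
})

test_that("splits are reproducible per run and differ across runs", {
  ids <- fake_ids(50)
  labels <- cohort_labels(10, 40)
  spec <- split_spec(20, seed = 5L)
  expect_identical(make_split(ids, labels, spec, 3L),
                   make_split(ids, labels, spec, 3L))
  expect_false(identical(make_split(ids, labels, spec, 3L),
                         make_split(ids, labels, spec, 4L)))
  # property: disjoint exhaustive partition across random cohorts
  set.seed(44)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    n_pos <- sample(2:(n - 2), 1)
    ids_i <- fake_ids(n)
    labels_i <- cohort_labels(n_pos, n - n_pos)
    sp <- make_split(ids_i, labels_i, split_spec(sample(seq_len(n - 1), 1)), i)
    expect_setequal(c(sp$train, sp$test), ids_i)
    expect_length(intersect(sp$train, sp$test), 0L)
  }
})

test_that("confusion metrics follow their defining identities", {
  m <- metrics_from_counts(tp = 13, fn = 0, tn = 98, fp = 16)
  expect_equal(m$sensitivity, 100)
  expect_equal(round_half_up(m$specificity, 1), 86.0)
  expect_equal(round_half_up(m$accuracy, 1), 87.4)
  perfect <- compute_metrics(c(1, -1, -1), c(1, -1, -1))
  expect_equal(perfect$accuracy, 100)
  expect_equal(perfect$error_rate, 0)
  timid <- compute_metrics(rep(-1, 5), c(1, 1, -1, -1, -1))
  expect_equal(timid$sensitivity, 0)
  expect_equal(timid$specificity, 100)
  # identity on random confusion tables
  set.seed(45)
  for (i in 1:50) {
    counts <- as.list(sample(0:30, 4, replace = TRUE))
    names(counts) <- c("tp", "fn", "tn", "fp")
    if (counts$tp + counts$fn == 0 || counts$tn + counts$fp == 0) next
    m <- do.call(metrics_from_counts, counts)
    p <- m$tp + m$fn; n <- m$tn + m$fp
    expect_equal(m$accuracy, (p * m$sensitivity + n * m$specificity) / (p + n),
                 tolerance = 1e-12)
    expect_equal(m$error_rate, 1 - m$accuracy / 100, tolerance = 1e-12)
  }
})

test_that("a class missing from truth flags the metric instead of zeroing it", {
  expect_warning(m <- compute_metrics(c(1, -1), c(-1, -1)), "sensitivity")
  expect_true(is.na(m$sensitivity))
  expect_false(is.na(m$specificity))
})

test_that("aggregation is the arithmetic column mean", {
  one <- data.frame(sensitivity = 80, specificity = 90, accuracy = 88)
  expect_equal(aggregate_metrics(one),
               list(sensitivity = 80, specificity = 90, accuracy = 88))
  same <- one[rep(1, 7), ]
  expect_equal(aggregate_metrics(same)$accuracy, 88)
  expect_error(aggregate_metrics(one[0, ]), "at least one")
  mixed <- data.frame(sensitivity = c(100, 50), specificity = c(80, 90),
                      accuracy = c(82, 86))
  expect_equal(aggregate_metrics(mixed),
               list(sensitivity = 75, specificity = 85, accuracy = 84))
})

test_that("half-up rounding matches table rendering conventions", {
  expect_identical(round_half_up(88.65, 1), 88.7)
  expect_identical(round_half_up(89.25, 1), 89.3)
  expect_identical(round_half_up(86.0, 1), 86.0)
  expect_identical(round_half_up(c(87.44, 87.45, 87.46), 1),
                   c(87.4, 87.5, 87.5))
})

test_that("experiments are reproducible and respect the feature subset", {
  feats <- featurize_cohort(small_cohort(6L, 14L, effect_size = 1))
  clf <- classifier_spec("nb")
  sp <- split_spec(8L, 5L, seed = 2L, feature_set = "p")
  r1 <- run_experiment(feats, clf, sp)
  r2 <- run_experiment(feats, clf, sp)
  expect_identical(r1$per_run, r2$per_run)
  expect_identical(nrow(r1$per_run), 5L)
  expect_equal(r1$averages$accuracy, mean(r1$per_run$accuracy))
  expect_equal(r1$averages$sensitivity, mean(r1$per_run$sensitivity))
  # P-only runs must not see V features: corrupting V columns changes nothing
  feats_v_mangled <- feats
  feats_v_mangled[c("v_mean", "v_sd", "v_mad", "v_l1", "v_l2")] <-
    feats_v_mangled[c("v_mean", "v_sd", "v_mad", "v_l1", "v_l2")] * 1000
  r3 <- run_experiment(feats_v_mangled, clf, sp)
  expect_identical(r1$per_run, r3$per_run)
  # but a pv run does depend on them
  sp_pv <- split_spec(8L, 5L, seed = 2L, feature_set = "pv")
  r4 <- run_experiment(feats, clf, sp_pv)
  expect_identical(ncol(r4$per_run), 9L)
})

test_that("report CSVs mirror the runs-plus-average table layout", {
  feats <- featurize_cohort(small_cohort(4L, 8L))
  report <- run_experiment(feats, classifier_spec("nb"),
                           split_spec(6L, 3L, seed = 1L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_report(report, path)
  tab <- utils::read.csv(path)
  expect_identical(nrow(tab), 4L)  # 3 runs + Average
  expect_identical(tab$run[4], "Average")
  expect_equal(tab$accuracy[4],
               round_half_up(report$averages$accuracy, 1))
  expect_true(file.exists(paste0(path, ".config.yml")))
})

test_that("evaluation refuses unlabelled cohorts", {
  feats <- featurize_cohort(small_cohort(2L, 3L))
  feats$label[2] <- NA
  expect_error(
    run_experiment(feats, classifier_spec("nb"), split_spec(2L, 2L)),
    "labelled"
  )
})
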