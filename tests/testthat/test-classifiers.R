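# single-feature tables for closed-form checks
one_feature_table <- function(pos, neg) {
  data.frame(
    sample_id = sprintf("s%02d", seq_len(length(pos) + length(neg))),
    label = c(rep(1, length(pos)), rep(-1, length(neg))),
    x = c(pos, neg)
  )
}

test_that("naive Bayes recovers closed-form class moments and priors", {
  tab <- one_feature_table(c(1, 2, 3), c(7, 8, 9))
  model <- train_classifier(tab, classifier_spec("nb"))
  p <- model$parameters
  expect_equal(p$priors, c(0.5, 0.5))
  expect_equal(p$means[, 1], c(2, 8))
  expect_equal(p$sds[1, 1], p$sds[2, 1])           # equal population sds
  expect_equal(p$sds[1, 1], sqrt(2 / 3), tolerance = 1e-12)
  # precision: distinct sorted values 1,2,3,7,8,9 -> mean gap 1.6
  expect_equal(p$precision, 1.6)
})

test_that("naive Bayes posteriors follow the Gaussian likelihoods", {
  tab <- one_feature_table(c(1, 2, 3), c(7, 8, 9))
  model <- train_classifier(tab, classifier_spec("nb"))
  query <- data.frame(x = 4)
  pred <- predict(model, query)
  expect_identical(pred$label, 1)  # log-density -3 vs -12 from class means
  expect_equal(pred$score_melanoma + pred$score_benign, 1, tolerance = 1e-12)
  # hand-computed posterior: exp(-3)/ (exp(-3) + exp(-12)) on z^2/2 terms
  s2 <- 2 / 3
  ll_pos <- dnorm(4, 2, sqrt(s2), log = TRUE)
  ll_neg <- dnorm(4, 8, sqrt(s2), log = TRUE)
  expect_equal(ll_pos - ll_neg, 9, tolerance = 1e-12)  # (-3) - (-12) on z^2/2
  expect_equal(pred$score_melanoma,
               1 / (1 + exp(ll_neg - ll_pos)), tolerance = 1e-12)
})

test_that("naive Bayes breaks exact posterior ties towards benign", {
  tab <- one_feature_table(c(-2, -1, -3), c(1, 2, 3))
  model <- train_classifier(tab, classifier_spec("nb"))
  pred <- predict(model, data.frame(x = 0))
  expect_equal(pred$score_melanoma, 0.5, tolerance = 1e-12)
  expect_identical(pred$label, -1)
})

test_that("naive Bayes floors a zero within-class sd at precision/6", {
  tab <- one_feature_table(c(5, 5, 5), c(8, 9, 10))
  model <- train_classifier(tab, classifier_spec("nb"))
  # distinct values 5,8,9,10 -> precision (3+1+1)/3; floor /6
  expect_equal(model$parameters$sds[1, 1], (5 / 3) / 6, tolerance = 1e-12)
})

test_that("naive Bayes predictions are scale-invariant away from the floor", {
  set.seed(31)
  feats <- toy_feature_table(8L, 12L, shift = 2)
  model <- train_classifier(feats, classifier_spec("nb"))
  scaled <- feats
  scaled[3:12] <- scaled[3:12] * 40
  model_s <- train_classifier(scaled, classifier_spec("nb"))
  query <- toy_feature_table(5L, 5L, shift = 1, seed = 77L)
  query_s <- query
  query_s[3:12] <- query_s[3:12] * 40
  expect_identical(predict(model, query)$label, predict(model_s, query_s)$label)
  expect_equal(predict(model, query)$score_melanoma,
               predict(model_s, query_s)$score_melanoma, tolerance = 1e-9)
})

test_that("naive Bayes labels agree with an independent implementation", {
  set.seed(32)
  feats <- toy_feature_table(15L, 25L, shift = 1.5)
  query <- toy_feature_table(10L, 10L, shift = 0.75, seed = 5L)
  mine <- predict(train_classifier(feats, classifier_spec("nb")), query)
  ref <- e1071::naiveBayes(
    x = feats[3:12], y = factor(feats$label, levels = c(-1, 1))
  )
  theirs <- predict(ref, query[3:12])
  # different sd divisor (n vs n-1) can flip only near-boundary cases
  agree <- mean(mine$label == ifelse(theirs == "1", 1, -1))
  expect_gte(agree, 0.9)
})

test_that("3-NN reproduces the hand-voted example", {
  tab <- one_feature_table(c(0, 0.1, 0.2), c(1.0, 1.1, 1.2))
  model <- train_classifier(tab, classifier_spec("knn", scale_features = FALSE))
  pred <- predict(model, data.frame(x = 0.15))
  expect_identical(pred$label, 1)  # all 3 nearest are positive
  expect_equal(pred$score_melanoma, 1)
  pred2 <- predict(model, data.frame(x = 0.9))
  expect_identical(pred2$label, -1)
  expect_equal(pred2$score_benign, 1)
  # mixed neighbourhood: 0.55 sees {0.2} overtaken by... distances:
  # 0.55 -> {0.2:0.35, 0.1:0.45, 1.0:0.45 tie, 0:0.55, ...}; the tie at
  # 0.45 is broken by training order, so neighbours are {0.2, 0.1, 1.0}
  pred3 <- predict(model, data.frame(x = 0.55))
  expect_identical(pred3$label, 1)
  expect_equal(pred3$score_melanoma, 2 / 3)
})

test_that("1-NN memorizes its own training set", {
  set.seed(33)
  feats <- toy_feature_table(8L, 10L, shift = 0.5)
  model <- train_classifier(feats, classifier_spec("knn", knn_k = 1L))
  expect_identical(predict(model, feats)$label, feats$label)
})

test_that("kNN scaling uses training ranges", {
  set.seed(34)
  feats <- toy_feature_table(8L, 10L, shift = 2)
  # one feature on a huge scale would dominate unscaled distances
  feats$p_l1 <- feats$p_l1 * 1e6
  m_scaled <- train_classifier(feats, classifier_spec("knn"))
  expect_false(is.null(m_scaled$scaling))
  expect_identical(m_scaled$scaling$lo[["p_l1"]], min(feats$p_l1))
  acc <- mean(predict(m_scaled, feats)$label == feats$label)
  expect_gte(acc, 0.9)
})

test_that("classifier specs validate their parameters", {
  expect_error(classifier_spec("knn", knn_k = 4L), "odd")
  expect_error(classifier_spec("mlp", mlp_hidden = 0L), "hidden")
  expect_error(classifier_spec("svm"), "arg")
})

test_that("training requires finite features and both classes", {
  feats <- toy_feature_table(5L, 5L)
  single <- feats[feats$label == -1, ]
  expect_error(train_classifier(single, classifier_spec("nb")), "both classes")
  feats$p_sd[2] <- NA
  expect_error(train_classifier(feats, classifier_spec("nb")), "finite")
  model <- train_classifier(toy_feature_table(5L, 5L), classifier_spec("nb"))
  expect_error(predict(model, data.frame(x = 1)), "missing column")
})

test_that("MLP with zero learning rate never moves its weights", {
  feats <- toy_feature_table(5L, 5L)
  spec0 <- classifier_spec("mlp", mlp_learning_rate = 0, mlp_epochs = 50L,
                           seed = 3L)
  m0 <- train_classifier(feats, spec0)
  spec_init <- classifier_spec("mlp", mlp_learning_rate = 0, mlp_epochs = 0L,
                               seed = 3L)
  m_init <- train_classifier(feats, spec_init)
  expect_identical(m0$parameters$w1, m_init$parameters$w1)
  expect_identical(m0$parameters$w2, m_init$parameters$w2)
})

test_that("MLP masters a well-separated training set within 500 epochs", {
  set.seed(35)
  feats <- toy_feature_table(100L, 100L, shift = 4)
  model <- train_classifier(feats, classifier_spec("mlp"))
  acc <- mean(predict(model, feats)$label == feats$label)
  expect_gte(acc, 0.99)
  expect_identical(dim(model$parameters$w1), c(11L, 6L))  # 10 inputs + bias
  expect_identical(dim(model$parameters$w2), c(7L, 2L))   # 6 hidden + bias
})

test_that("all classifiers are bit-deterministic given data and spec", {
  feats <- toy_feature_table(6L, 9L)
  for (kind in c("nb", "knn", "mlp")) {
    spec <- classifier_spec(kind, mlp_epochs = 20L, seed = 7L)
    m1 <- train_classifier(feats, spec)
    m2 <- train_classifier(feats, spec)
    expect_identical(m1$parameters, m2$parameters)
    expect_identical(predict(m1, feats), predict(m2, feats))
  }
})

test_that("posterior scores sum to one for every classifier", {
  set.seed(36)
  feats <- toy_feature_table(6L, 9L)
  query <- toy_feature_table(4L, 4L, seed = 2L)
  for (kind in c("nb", "knn", "mlp")) {
    model <- train_classifier(feats, classifier_spec(kind, mlp_epochs = 20L))
    pred <- predict(model, query)
    expect_equal(pred$score_melanoma + pred$score_benign, rep(1, 8L),
                 tolerance = 1e-12)
  }
})
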