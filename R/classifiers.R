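#' Specify a classifier configuration
#'
#' The three classifiers of the pipeline, each with the configuration
#' the original evaluation used:
#'
#' * `"nb"` — Gaussian naive Bayes: class priors from class frequencies,
#'   one normal density per feature and class, with the standard
#'   deviation floored at `precision / 6` where `precision` is the mean
#'   gap between consecutive distinct sorted training values of that
#'   feature (the numeric-estimator behaviour of the classic Java
#'   machine-learning workbench this mirrors).
#' * `"knn"` — k-nearest-neighbour, brute-force Euclidean search,
#'   unweighted majority vote, k = 3 by default.
#' * `"mlp"` — one-hidden-layer perceptron (10 inputs, 6 hidden units, 2
#'   outputs by default), sigmoid units throughout, online
#'   back-propagation with momentum, learning rate 0.3, momentum 0.2,
#'   500 epochs, weights initialized uniformly in `[-0.5, 0.5]`.
#'
#' Features are min-max scaled to `[0, 1]` using training ranges for
#' knn and mlp (distance- and gradient-based learners); naive Bayes is
#' scale-adaptive and uses raw features.
#'
#' @param kind `"nb"`, `"knn"` or `"mlp"`.
#' @param knn_k Odd neighbour count >= 1.
#' @param mlp_hidden Hidden-layer size.
#' @param mlp_learning_rate,mlp_momentum,mlp_epochs Back-propagation
#'   hyper-parameters.
#' @param seed Integer seed for weight initialization.
#' @param scale_features Min-max scale features to `[0, 1]` by training
#'   ranges; default on for knn/mlp, off for nb.
#' @param nb_sd_floor_factor The sd floor is `precision * factor`;
#'   default 1/6.
#' @return A `classifier_spec` object.
#' @export
classifier_spec <- function(kind = c("nb", "knn", "mlp"),
                            knn_k = 3L, mlp_hidden = 6L,
                            mlp_learning_rate = 0.3, mlp_momentum = 0.2,
                            mlp_epochs = 500L, seed = 0L,
                            scale_features = NULL,
                            nb_sd_floor_factor = 1 / 6) {
  kind <- match.arg(kind)
  knn_k <- as.integer(knn_k)
  if (is.na(knn_k) || knn_k < 1L || knn_k %% 2L == 0L) {
    stop("`knn_k` must be an odd integer >= 1", call. = FALSE)
  }
  mlp_hidden <- as.integer(mlp_hidden)
  mlp_epochs <- as.integer(mlp_epochs)
  if (is.na(mlp_hidden) || mlp_hidden < 1L ||
      is.na(mlp_epochs) || mlp_epochs < 0L ||
      mlp_learning_rate < 0 || mlp_momentum < 0) {
    stop("mlp parameters must be non-negative (hidden units >= 1)",
         call. = FALSE)
  }
  if (is.null(scale_features)) {
    scale_features <- kind %in% c("knn", "mlp")
  }
  structure(
    list(
      kind = kind, knn_k = knn_k, mlp_hidden = mlp_hidden,
      mlp_learning_rate = mlp_learning_rate, mlp_momentum = mlp_momentum,
      mlp_epochs = mlp_epochs, seed = as.integer(seed),
      scale_features = isTRUE(scale_features),
      nb_sd_floor_factor = nb_sd_floor_factor
    ),
    class = "classifier_spec"
  )
}

#' @export
print.classifier_spec <- function(x, ...) {
  extra <- switch(x$kind,
    nb = sprintf("sd floor factor %g", x$nb_sd_floor_factor),
    knn = sprintf("k = %d", x$knn_k),
    mlp = sprintf("hidden %d, lr %g, momentum %g, epochs %d, seed %d",
                  x$mlp_hidden, x$mlp_learning_rate, x$mlp_momentum,
                  x$mlp_epochs, x$seed)
  )
  cat(sprintf("<classifier_spec> %s (%s), scaling %s\n",
              x$kind, extra, ifelse(x$scale_features, "on", "off")))
  invisible(x)
}

# classes in fixed order: +1 melanoma (positive), -1 benign
MODEL_CLASSES <- c(1, -1)

# split a feature table into the numeric design matrix + label vector
design_matrix <- function(features, feature_names = NULL) {
  stopifnot(is.data.frame(features))
  if (is.null(feature_names)) {
    feature_names <- setdiff(names(features), c("sample_id", "label"))
  }
  missing_cols <- setdiff(feature_names, names(features))
  if (length(missing_cols) > 0L) {
    stop("feature table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  x <- as.matrix(features[feature_names])
  storage.mode(x) <- "double"
  if (anyNA(x) || any(!is.finite(x))) {
    stop("non-finite feature values", call. = FALSE)
  }
  x
}

# min-max scale columns by stored training ranges; constant training
# columns map to 0
apply_scaling <- function(x, lo, hi) {
  rng <- hi - lo
  rng[rng == 0] <- 1
  sweep(sweep(x, 2L, lo, "-"), 2L, rng, "/")
}

# numeric-estimator precision: mean gap between consecutive distinct
# sorted values of one feature over the whole training set
feature_precision <- function(values) {
  v <- sort(unique(values))
  if (length(v) < 2L) return(0.01)
  mean(diff(v))
}

#' Train a classifier on a labelled feature table
#'
#' @param features Data frame with a `label` column (+1/-1 coding, both
#'   classes present) and numeric feature columns; typically the output
#'   of [featurize_cohort()], possibly restricted to the P or V columns.
#' @param spec A [classifier_spec()].
#' @return A `melaspec_model`; use [predict.melaspec_model()] to
#'   classify new samples and [write_model()] to save it.
#' @export
train_classifier <- function(features, spec = classifier_spec("nb")) {
  stopifnot(inherits(spec, "classifier_spec"))
  feature_names <- setdiff(names(features), c("sample_id", "label"))
  x <- design_matrix(features, feature_names)
  y <- features$label
  if (anyNA(y)) {
    stop("training set contains unlabelled samples", call. = FALSE)
  }
  if (!all(MODEL_CLASSES %in% y)) {
    stop("training set must contain both classes (+1 and -1)",
         call. = FALSE)
  }
  scaling <- NULL
  if (spec$scale_features) {
    scaling <- list(lo = apply(x, 2L, min), hi = apply(x, 2L, max))
    x <- apply_scaling(x, scaling$lo, scaling$hi)
  }
  parameters <- switch(spec$kind,
    nb = train_nb(x, y, spec),
    knn = list(train_x = x, train_labels = y),
    mlp = train_mlp(x, y, spec)
  )
  structure(
    list(
      spec = spec,
      feature_names = feature_names,
      classes = MODEL_CLASSES,
      scaling = scaling,
      n_train = nrow(x),
      parameters = parameters
    ),
    class = "melaspec_model"
  )
}

train_nb <- function(x, y, spec) {
  dimnames(x) <- NULL
  priors <- vapply(MODEL_CLASSES, function(cl) mean(y == cl), numeric(1))
  precision <- apply(x, 2L, feature_precision)
  sd_floor <- pmax(precision * spec$nb_sd_floor_factor, .Machine$double.eps)
  moments <- lapply(MODEL_CLASSES, function(cl) {
    xc <- x[y == cl, , drop = FALSE]
    mu <- colMeans(xc)
    # population sd (divisor n), consistent with the image statistics
    sdv <- sqrt(colMeans(sweep(xc, 2L, mu, "-")^2))
    list(mean = mu, sd = pmax(sdv, sd_floor))
  })
  list(
    priors = priors,
    means = rbind(moments[[1]]$mean, moments[[2]]$mean),
    sds = rbind(moments[[1]]$sd, moments[[2]]$sd),
    precision = precision
  )
}

sigmoid <- function(z) 1 / (1 + exp(-z))

train_mlp <- function(x, y, spec) {
  dimnames(x) <- NULL
  d <- ncol(x)
  h <- spec$mlp_hidden
  old_seed <- get0(".Random.seed", envir = globalenv())
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  })
  set.seed(spec$seed)
  # +1 row for the bias unit; 2 output units one-hot over (melanoma, benign)
  w1 <- matrix(runif((d + 1) * h, -0.5, 0.5), d + 1, h)
  w2 <- matrix(runif((h + 1) * 2, -0.5, 0.5), h + 1, 2)
  dw1 <- matrix(0, d + 1, h)
  dw2 <- matrix(0, h + 1, 2)
  lr <- spec$mlp_learning_rate
  mom <- spec$mlp_momentum
  targets <- cbind(as.numeric(y == 1), as.numeric(y == -1))
  n <- nrow(x)
  for (epoch in seq_len(spec$mlp_epochs)) {
    for (s in seq_len(n)) {
      a0 <- c(x[s, ], 1)
      hidden <- sigmoid(drop(a0 %*% w1))
      a1 <- c(hidden, 1)
      out <- sigmoid(drop(a1 %*% w2))
      # squared-error deltas for sigmoid outputs
      delta_o <- (targets[s, ] - out) * out * (1 - out)
      delta_h <- hidden * (1 - hidden) * drop(w2[seq_len(h), ] %*% delta_o)
      dw2 <- lr * outer(a1, delta_o) + mom * dw2
      dw1 <- lr * outer(a0, delta_h) + mom * dw1
      w2 <- w2 + dw2
      w1 <- w1 + dw1
    }
  }
  list(w1 = w1, w2 = w2)
}

#' @export
print.melaspec_model <- function(x, ...) {
  cat(sprintf(
    "<melaspec_model> %s trained on %d samples, %d features (%s)\n",
    x$spec$kind, x$n_train, length(x$feature_names),
    paste(x$feature_names, collapse = ", ")
  ))
  invisible(x)
}

#' Predict class labels for new samples
#'
#' Scores are per-class and sum to 1 for every query: posterior
#' probabilities for naive Bayes, vote fractions for k-NN, normalized
#' output activations for the network. The predicted label is the
#' argmax; exact ties resolve to benign (-1), the conservative call.
#'
#' @param object A `melaspec_model`.
#' @param features Data frame containing the model's feature columns
#'   (extra columns, including `sample_id`/`label`, are ignored).
#' @param ... Unused.
#' @return Data frame with columns `label` (+1/-1), `score_melanoma`,
#'   `score_benign`, one row per input row.
#' @export
predict.melaspec_model <- function(object, features, ...) {
  x <- design_matrix(features, object$feature_names)
  if (ncol(x) != length(object$feature_names)) {
    stop("feature dimension mismatch", call. = FALSE)
  }
  if (!is.null(object$scaling)) {
    x <- apply_scaling(x, object$scaling$lo, object$scaling$hi)
  }
  scores <- switch(object$spec$kind,
    nb = predict_nb(object, x),
    knn = predict_knn(object, x),
    mlp = predict_mlp(object, x)
  )
  label <- ifelse(scores[, 1] > scores[, 2], 1, -1)
  data.frame(
    label = label,
    score_melanoma = scores[, 1],
    score_benign = scores[, 2]
  )
}

predict_nb <- function(model, x) {
  p <- model$parameters
  n <- nrow(x)
  loglik <- vapply(1:2, function(ci) {
    ll <- matrix(
      dnorm(as.vector(x), mean = rep(p$means[ci, ], each = n),
            sd = rep(p$sds[ci, ], each = n), log = TRUE),
      nrow = n
    )
    log(p$priors[ci]) + rowSums(ll)
  }, numeric(n))
  loglik <- matrix(loglik, ncol = 2L)
  # normalize in log space for numerical stability
  mx <- apply(loglik, 1L, max)
  un <- exp(loglik - mx)
  un / rowSums(un)
}

predict_knn <- function(model, x) {
  tr <- model$parameters$train_x
  ty <- model$parameters$train_labels
  k <- model$spec$knn_k
  t(apply(x, 1L, function(q) {
    d2 <- colSums((t(tr) - q)^2)
    # stable order: distance ties broken by training-set position
    nn <- order(d2, seq_along(d2))[seq_len(k)]
    votes_mel <- sum(ty[nn] == 1)
    c(votes_mel, k - votes_mel) / k
  }))
}

predict_mlp <- function(model, x) {
  p <- model$parameters
  h <- sigmoid(cbind(x, 1) %*% p$w1)
  out <- sigmoid(cbind(h, 1) %*% p$w2)
  out / rowSums(out)
}
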