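# Per-test 3-class scoring. Two classifier families: a linear soft-margin
# SVM multiclass scheme (binary subproblems solved by the LIBSVM binding in
# e1071 with default settings apart from the linear kernel, composed by
# LIBSVM's pairwise voting; decision functions stored explicitly as (w, b)
# pairs) and a three-layer backpropagation network trained by full-batch
# gradient descent. Plus the validation protocols: leave-one-subject-out
# cross-validation and the accuracy-vs-training-set-size curve.

SCORE_CLASSES <- 0:2

#' Construct a labeled feature dataset
#'
#' @param x numeric feature matrix (rows = recordings) or a list of
#'   `feature_vector`s.
#' @param labels integer scores in `{0, 1, 2}`, one per row.
#' @param subjects subject id per row.
#' @param test_id registry key the features belong to.
#' @return an object of class `labeled_dataset`.
#' @export
labeled_dataset <- function(x, labels, subjects, test_id) {
  if (is.list(x) && !is.matrix(x)) x <- feature_matrix(x)
  x <- as.matrix(x)
  labels <- as.integer(labels)
  subjects <- as.character(subjects)
  if (nrow(x) != length(labels) || nrow(x) != length(subjects))
    stop("labeled_dataset: rows, labels and subjects must align")
  if (!all(labels %in% SCORE_CLASSES))
    stop("labeled_dataset: labels must be 0, 1 or 2")
  if (!all(is.finite(x)))
    stop("labeled_dataset: non-finite feature values")
  structure(list(x = x, labels = labels, subjects = subjects,
                 test_id = as.character(test_id)),
            class = "labeled_dataset")
}

#' Train a linear multiclass SVM scorer
#'
#' Linear-kernel soft-margin SVMs trained with library default settings
#' apart from the kernel, composed into a 3-class scorer by LIBSVM's
#' pairwise (one-against-one) voting scheme; no feature scaling is applied.
#' Each binary decision function is stored explicitly as a `(w, b)` pair so
#' fitted models serialize to plain JSON.
#'
#' @param data a [labeled_dataset()].
#' @param cost soft-margin constant passed to the solver (library default 1).
#' @return an `fma_model` of kind `"svm"`.
#' @export
train_svm <- function(data, cost = 1) {
  stopifnot(inherits(data, "labeled_dataset"))
  present <- sort(unique(data$labels))
  if (length(present) < 2)
    stop("train_svm: training data contains a single class")
  d <- ncol(data$x)
  pairs <- list()
  for (a in SCORE_CLASSES) for (bcl in SCORE_CLASSES) {
    if (bcl <= a || !(a %in% present) || !(bcl %in% present)) next
    rows <- data$labels %in% c(a, bcl)
    ya <- factor(ifelse(data$labels[rows] == a, "a", "b"),
                 levels = c("a", "b"))
    fit <- e1071::svm(data$x[rows, , drop = FALSE], ya,
                      type = "C-classification", kernel = "linear",
                      cost = cost, scale = FALSE)
    w <- as.numeric(t(fit$SV) %*% fit$coefs)
    b0 <- -fit$rho
    # orient the decision so positive means "class a"
    dv <- data$x[rows, , drop = FALSE] %*% w + b0
    if (mean(dv[ya == "a"]) < mean(dv[ya == "b"])) {
      w <- -w; b0 <- -b0
    }
    pairs[[length(pairs) + 1L]] <- list(a = a, b = bcl, w = w, b0 = b0)
  }
  structure(list(kind = "svm", test_id = data$test_id, dimension = d,
                 feature_names = colnames(data$x), pairs = pairs,
                 meta = list(n_per_class = table(factor(data$labels,
                                                        SCORE_CLASSES)))),
            class = c("fma_svm", "fma_model"))
}

# Pairwise decision values for probe rows: one column per trained class
# pair, positive meaning the pair's lower class.
svm_decision_values <- function(object, x) {
  x <- model_input(object, x)
  dv <- vapply(object$pairs, function(p)
    as.numeric(x %*% p$w + p$b0), numeric(nrow(x)))
  if (is.null(dim(dv))) dv <- matrix(dv, nrow = nrow(x))
  colnames(dv) <- vapply(object$pairs, function(p)
    paste0(p$a, "/", p$b), character(1))
  dv
}

sigmoid <- function(z) 1 / (1 + exp(-z))

#' Train a three-layer backpropagation network scorer
#'
#' Network sized input = feature dimension, output = 3 (one node per score),
#' hidden = `round((input + 3) / 2)` -- about halfway between input and
#' output width. Sigmoid activations, squared-error objective, full-batch
#' gradient descent, seeded uniform (Xavier-style) initialization. As a
#' numerical conditioning device the network applies a fixed affine
#' standardization of its inputs, estimated from the training data and
#' stored in the model; the feature vectors themselves are never rescaled.
#' Deterministic given the seed.
#'
#' @param data a [labeled_dataset()].
#' @param seed integer RNG seed for weight initialization.
#' @param epochs number of full-batch gradient steps (`> 0`).
#' @param learning_rate gradient-descent step size (`> 0`).
#' @param hidden hidden-layer width override (default the halfway rule).
#' @return an `fma_model` of kind `"bnn"`.
#' @export
train_bnn <- function(data, seed = 1, epochs = 1000, learning_rate = 0.5,
                      hidden = NULL) {
  stopifnot(inherits(data, "labeled_dataset"))
  if (length(unique(data$labels)) < 2)
    stop("train_bnn: training data contains a single class")
  if (epochs <= 0) stop("train_bnn: epochs must be > 0")
  if (learning_rate <= 0) stop("train_bnn: learning_rate must be > 0")
  d <- ncol(data$x)
  h <- if (is.null(hidden)) as.integer(round((d + 3) / 2)) else
    as.integer(hidden)
  if (h < 1) stop("train_bnn: hidden width must be >= 1")
  n <- nrow(data$x)

  mu <- colMeans(data$x)
  sdev <- apply(data$x, 2, stats::sd)
  sdev[!is.finite(sdev) | sdev < 1e-12] <- 1
  Z <- sweep(sweep(data$x, 2, mu), 2, sdev, "/")
  Tm <- matrix(0, n, 3)
  Tm[cbind(seq_len(n), data$labels + 1L)] <- 1

  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(as.integer(seed))
  r1 <- sqrt(6 / (d + h))
  r2 <- sqrt(6 / (h + 3))
  W1 <- matrix(runif(d * h, -r1, r1), d, h)
  b1 <- rep(0, h)
  W2 <- matrix(runif(h * 3, -r2, r2), h, 3)
  b2 <- rep(0, 3)

  for (ep in seq_len(epochs)) {
    H <- sigmoid(sweep(Z %*% W1, 2, b1, "+"))
    O <- sigmoid(sweep(H %*% W2, 2, b2, "+"))
    # squared-error objective: L = sum((O - T)^2) / (2 n)
    dO <- (O - Tm) * O * (1 - O) / n
    gW2 <- t(H) %*% dO
    gb2 <- colSums(dO)
    dH <- (dO %*% t(W2)) * H * (1 - H)
    gW1 <- t(Z) %*% dH
    gb1 <- colSums(dH)
    W2 <- W2 - learning_rate * gW2
    b2 <- b2 - learning_rate * gb2
    W1 <- W1 - learning_rate * gW1
    b1 <- b1 - learning_rate * gb1
  }
  structure(list(kind = "bnn", test_id = data$test_id, dimension = d,
                 feature_names = colnames(data$x), hidden = h,
                 W1 = W1, b1 = b1, W2 = W2, b2 = b2, mu = mu, sd = sdev,
                 meta = list(seed = as.integer(seed), epochs = epochs,
                             learning_rate = learning_rate,
                             n_per_class = table(factor(data$labels,
                                                        SCORE_CLASSES)))),
            class = c("fma_bnn", "fma_model"))
}

model_input <- function(object, x) {
  if (inherits(x, "feature_vector")) x <- matrix(x$values, 1)
  if (is.null(dim(x))) x <- matrix(x, 1)
  x <- as.matrix(x)
  if (ncol(x) != object$dimension)
    stop(sprintf("predict: feature dimension %d does not match model dimension %d",
                 ncol(x), object$dimension))
  x
}

#' Predict movement scores
#'
#' SVM: the class winning the most pairwise votes. BNN: the output node with
#' the highest activation. Ties break to the lowest score.
#'
#' @param object a fitted `fma_model`.
#' @param x a `feature_vector`, numeric vector, or matrix of rows to score.
#' @param ... unused.
#' @return integer score(s) in `{0, 1, 2}`.
#' @export
predict.fma_model <- function(object, x, ...) {
  x <- model_input(object, x)
  act <- model_activations(object, x)
  as.integer(SCORE_CLASSES[max.col(act, ties.method = "first")])
}

model_activations <- function(object, x) {
  if (object$kind == "svm") {
    votes <- matrix(0, nrow(x), length(SCORE_CLASSES),
                    dimnames = list(NULL, SCORE_CLASSES))
    for (p in object$pairs) {
      dv <- as.numeric(x %*% p$w + p$b0)
      win <- ifelse(dv >= 0, p$a, p$b)
      for (k in SCORE_CLASSES)
        votes[, as.character(k)] <- votes[, as.character(k)] + (win == k)
    }
    votes
  } else {
    z <- sweep(sweep(x, 2, object$mu), 2, object$sd, "/")
    H <- sigmoid(sweep(z %*% object$W1, 2, object$b1, "+"))
    sigmoid(sweep(H %*% object$W2, 2, object$b2, "+"))
  }
}

#' @export
print.fma_model <- function(x, ...) {
  cat(sprintf("<fma_model:%s> test=%s dim=%d", x$kind, x$test_id,
              x$dimension))
  if (x$kind == "bnn") cat(sprintf(" hidden=%d", x$hidden))
  cat("\n  training n per class:",
      paste(sprintf("%s:%d", names(x$meta$n_per_class), x$meta$n_per_class),
            collapse = " "), "\n")
  invisible(x)
}

#' Classification accuracy
#'
#' @param predictions,truth equal-length score vectors.
#' @return fraction of equal entries.
#' @export
accuracy <- function(predictions, truth) {
  if (length(predictions) != length(truth))
    stop("accuracy: length mismatch")
  if (!length(truth)) stop("accuracy: empty input")
  mean(predictions == truth)
}

train_model <- function(data, trainer, seed = 1, ...) {
  switch(match.arg(trainer, c("svm", "bnn")),
         svm = train_svm(data, ...),
         bnn = train_bnn(data, seed = seed, ...))
}

subset_dataset <- function(data, idx) {
  labeled_dataset(data$x[idx, , drop = FALSE], data$labels[idx],
                  data$subjects[idx], data$test_id)
}

# Seeded subsample of at most m rows per class (all rows of a class when it
# has fewer than m).
subsample_per_class <- function(data, m, seed) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                           globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(as.integer(seed))
  idx <- unlist(lapply(SCORE_CLASSES, function(k) {
    rows <- which(data$labels == k)
    if (length(rows) <= m) rows else sort(sample(rows, m))
  }))
  sort(idx)
}

#' Leave-one-subject-out cross-validation
#'
#' For each subject, trains on all other subjects' recordings and tests on
#' that subject's; the number of folds equals the number of subjects. Folds
#' whose training partition is single-class are skipped with a warning.
#'
#' @param data a [labeled_dataset()] with at least 2 subjects.
#' @param trainer `"svm"` or `"bnn"`.
#' @param instances_per_class when non-`NULL`, each fold's training set is a
#'   seeded subsample of this many instances per class (the five-per-class
#'   regime found to maximize accuracy).
#' @param seed seed driving subsampling and BNN initialization per fold.
#' @param ... passed to the trainer.
#' @return list with `per_subject` (named accuracy vector, `NA` for skipped
#'   folds), `mean`, and `predictions` (held-out score per data row, `NA`
#'   for skipped folds).
#' @export
crossval_by_subject <- function(data, trainer = c("svm", "bnn"),
                                instances_per_class = NULL, seed = 1, ...) {
  stopifnot(inherits(data, "labeled_dataset"))
  trainer <- match.arg(trainer)
  subjects <- unique(data$subjects)
  if (length(subjects) < 2)
    stop("crossval_by_subject: need at least 2 subjects")
  acc <- stats::setNames(rep(NA_real_, length(subjects)), subjects)
  predictions <- rep(NA_integer_, nrow(data$x))
  for (i in seq_along(subjects)) {
    s <- subjects[i]
    test_idx <- which(data$subjects == s)
    train_idx <- which(data$subjects != s)
    fold_seed <- as.integer(seed) + i
    train <- subset_dataset(data, train_idx)
    if (!is.null(instances_per_class))
      train <- subset_dataset(train,
                              subsample_per_class(train, instances_per_class,
                                                  fold_seed))
    if (length(unique(train$labels)) < 2) {
      warning(sprintf("crossval_by_subject: fold '%s' has single-class training data; skipped", s))
      next
    }
    model <- train_model(train, trainer, seed = fold_seed, ...)
    pred <- predict(model, data$x[test_idx, , drop = FALSE])
    predictions[test_idx] <- pred
    acc[s] <- accuracy(pred, data$labels[test_idx])
  }
  list(per_subject = acc, mean = mean(acc, na.rm = TRUE),
       predictions = predictions)
}

#' Accuracy as a function of training-set size
#'
#' For each size `m`, repeatedly subsamples `m` training instances per class
#' (seeded), trains, evaluates on the held-out remainder and averages over
#' repetitions. Reproduces the accuracy-vs-training-instances shape study on
#' synthetic cohorts.
#'
#' @param data a [labeled_dataset()].
#' @param instances_per_class integer vector of training sizes per class.
#' @param reps repetitions per size.
#' @param seed RNG seed.
#' @param trainer `"svm"` or `"bnn"`.
#' @param ... passed to the trainer.
#' @return data.frame with columns `instances_per_class` and `accuracy`.
#' @export
training_curve <- function(data, instances_per_class, reps = 10, seed = 1,
                           trainer = "svm", ...) {
  stopifnot(inherits(data, "labeled_dataset"))
  counts <- table(factor(data$labels, SCORE_CLASSES))
  out <- numeric(length(instances_per_class))
  for (j in seq_along(instances_per_class)) {
    m <- instances_per_class[j]
    if (any(counts < m))
      stop("training_curve: fewer than ", m, " examples in some class")
    accs <- numeric(reps)
    for (r in seq_len(reps)) {
      rs <- as.integer(seed) + 1000L * j + r
      tr_idx <- subsample_per_class(data, m, rs)
      te_idx <- setdiff(seq_len(nrow(data$x)), tr_idx)
      train <- subset_dataset(data, tr_idx)
      model <- train_model(train, trainer, seed = rs, ...)
      if (length(te_idx)) {
        pred <- predict(model, data$x[te_idx, , drop = FALSE])
        accs[r] <- accuracy(pred, data$labels[te_idx])
      } else {
        pred <- predict(model, data$x)
        accs[r] <- accuracy(pred, data$labels)
      }
    }
    out[j] <- mean(accs)
  }
  data.frame(instances_per_class = instances_per_class, accuracy = out)
}

#' Save fitted models as a versioned JSON document
#'
#' @param models a named list of `fma_model`s (or a single model).
#' @param path output JSON file.
#' @return `path`, invisibly.
#' @export
save_models <- function(models, path) {
  if (inherits(models, "fma_model"))
    models <- stats::setNames(list(models), models$test_id)
  ser <- lapply(models, function(m) {
    u <- unclass(m)
    u$meta$n_per_class <- as.list(u$meta$n_per_class)
    u
  })
  jsonlite::write_json(list(format = "fma-models", version = 1L,
                            models = ser),
                       path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Load models saved by [save_models()]
#'
#' @param path JSON file.
#' @return named list of `fma_model`s keyed by test id.
#' @export
load_models <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(doc$format, "fma-models"))
    stop("load_models: not an fma-models document")
  lapply(doc$models, function(m) {
    if (m$kind == "svm") {
      if (is.data.frame(m$pairs)) {
        m$pairs <- lapply(seq_len(nrow(m$pairs)), function(i)
          list(a = m$pairs$a[i], b = m$pairs$b[i],
               w = as.numeric(m$pairs$w[[i]]), b0 = m$pairs$b0[i]))
      } else {
        m$pairs <- lapply(m$pairs, function(p)
          list(a = p$a, b = p$b, w = as.numeric(p$w), b0 = p$b0))
      }
      class(m) <- c("fma_svm", "fma_model")
    } else {
      m$W1 <- matrix(as.numeric(m$W1), m$dimension, m$hidden)
      m$W2 <- matrix(as.numeric(m$W2), m$hidden, 3)
      m$b1 <- as.numeric(m$b1); m$b2 <- as.numeric(m$b2)
      m$mu <- stats::setNames(as.numeric(m$mu), m$feature_names)
      m$sd <- stats::setNames(as.numeric(m$sd), m$feature_names)
      class(m) <- c("fma_bnn", "fma_model")
    }
    m
  })
}
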