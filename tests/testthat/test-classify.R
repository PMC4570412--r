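test_that("SVM separates well-separated clusters and validates input", {
  d <- make_cluster_dataset(n_per_class = 5, sd = 0.01, sep = 10, seed = 1)
  m <- train_svm(d)
  expect_equal(accuracy(predict(m, d$x), d$labels), 1.0)
  expect_error(predict(m, c(1, 2)), "dimension")
  single <- labeled_dataset(d$x[d$labels == 1, ], rep(1, 5),
                            d$subjects[d$labels == 1], "toy")
  expect_error(train_svm(single), "single class")
})

test_that("duplicating separable training data leaves the decision functions unchanged", {
  d <- make_cluster_dataset(n_per_class = 5, sd = 0.01, sep = 10, seed = 2)
  dup <- labeled_dataset(rbind(d$x, d$x), c(d$labels, d$labels),
                         c(d$subjects, d$subjects), d$test_id)
  m1 <- train_svm(d)
  m2 <- train_svm(dup)
  set.seed(5)
  probe <- matrix(runif(60 * 3, -5, 25), 60, 3)
  dv1 <- fmassess:::svm_decision_values(m1, probe)
  dv2 <- fmassess:::svm_decision_values(m2, probe)
  expect_equal(dv1, dv2, tolerance = 1e-6)
  expect_equal(predict(m1, probe), predict(m2, probe))
})

test_that("SVM predictions recover cluster membership like a nearest-centroid oracle", {
  d <- make_cluster_dataset(n_per_class = 6, sd = 0.05, sep = 8, seed = 3)
  m <- train_svm(d)
  centers <- rbind(colMeans(d$x[d$labels == 0, ]),
                   colMeans(d$x[d$labels == 1, ]),
                   colMeans(d$x[d$labels == 2, ]))
  set.seed(9)
  probe <- centers[rep(1:3, each = 20), ] + matrix(rnorm(180, 0, 0.05),
                                                   60, 3)
  oracle <- apply(probe, 1, function(p)
    which.min(colSums((t(centers) - p)^2)) - 1)
  expect_equal(predict(m, probe), as.integer(oracle))
  # training point of class 2 predicts 2
  expect_equal(predict(m, d$x[d$labels == 2, ][1, ]), 2L)
})

test_that("BNN sizing follows the halfway rule and training is seed-deterministic", {
  d7 <- make_cluster_dataset(n_per_class = 4, d = 7, sd = 0.01, sep = 10,
                             seed = 4)
  m <- train_bnn(d7, seed = 1, epochs = 5)
  expect_equal(m$hidden, 5L)   # round((7 + 3) / 2)

  m1 <- train_bnn(d7, seed = 11, epochs = 50)
  m2 <- train_bnn(d7, seed = 11, epochs = 50)
  expect_identical(m1$W1, m2$W1)
  expect_identical(m1$W2, m2$W2)
  m3 <- train_bnn(d7, seed = 12, epochs = 50)
  expect_false(identical(m1$W1, m3$W1))

  expect_error(train_bnn(d7, epochs = 0), "epochs")
  expect_error(train_bnn(d7, learning_rate = -1), "learning_rate")
})

test_that("BNN gradient descent matches an independent per-sample implementation", {
  d <- make_cluster_dataset(n_per_class = 3, d = 4, sd = 0.5, sep = 2,
                            seed = 6)
  m <- train_bnn(d, seed = 3, epochs = 40, learning_rate = 0.3)
  o <- oracle_bnn_weights(d$x, d$labels, seed = 3, epochs = 40, lr = 0.3,
                          hidden = m$hidden)
  expect_equal(m$W1, o$W1, tolerance = 1e-10)
  expect_equal(m$b1, o$b1, tolerance = 1e-10)
  expect_equal(m$W2, o$W2, tolerance = 1e-10)
  expect_equal(m$b2, o$b2, tolerance = 1e-10)
})

test_that("BNN converges to perfect training accuracy on separable clusters", {
  d <- make_cluster_dataset(n_per_class = 5, sd = 0.01, sep = 10, seed = 7)
  m <- train_bnn(d, seed = 1, epochs = 2000, learning_rate = 0.5)
  expect_equal(accuracy(predict(m, d$x), d$labels), 1.0)
})

test_that("prediction ties break to the lowest score", {
  d <- make_cluster_dataset(n_per_class = 4, seed = 8)
  m <- train_bnn(d, seed = 1, epochs = 10)
  # degenerate network: all-equal output activations
  m$W1[] <- 0; m$b1[] <- 0; m$W2[] <- 0; m$b2[] <- 0
  expect_equal(predict(m, d$x[1, ]), 0L)
})

test_that("label permutation permutes predictions identically", {
  d <- make_cluster_dataset(n_per_class = 5, sd = 0.01, sep = 10, seed = 10)
  perm <- c(1L, 2L, 0L)   # relabel 0->1, 1->2, 2->0
  dp <- labeled_dataset(d$x, perm[d$labels + 1], d$subjects, d$test_id)
  set.seed(2)
  probe <- rbind(d$x, d$x + matrix(rnorm(length(d$x), 0, 0.02),
                                   nrow(d$x)))
  for (trainer in c("svm", "bnn")) {
    fit <- function(dat) if (trainer == "svm") train_svm(dat) else
      train_bnn(dat, seed = 1, epochs = 2000)
    m <- fit(d)
    mp <- fit(dp)
    expect_equal(predict(mp, probe), perm[predict(m, probe) + 1],
                 info = trainer)
  }
})

test_that("accuracy is the fraction of matching scores", {
  expect_equal(accuracy(c(0, 1, 2), c(0, 1, 2)), 1.0)
  expect_equal(accuracy(c(0, 0, 0), c(1, 2, 1)), 0.0)
  expect_equal(accuracy(c(rep(1, 29), 0), c(rep(1, 29), 1)), 29 / 30)
  expect_error(accuracy(c(1, 2), c(1)), "length")
})

test_that("subject-wise cross-validation builds one fold per subject", {
  d <- make_cluster_dataset(n_per_class = 6, sd = 0.01, sep = 10, seed = 12,
                            subjects = rep(c("a", "b", "c"), 6))
  cv <- crossval_by_subject(d, "svm")
  expect_named(cv$per_subject, c("a", "b", "c"))
  expect_equal(unname(cv$per_subject), c(1, 1, 1))
  expect_equal(cv$mean, 1)

  one <- labeled_dataset(d$x, d$labels, rep("a", nrow(d$x)), "toy")
  expect_error(crossval_by_subject(one, "svm"), "at least 2 subjects")
})

test_that("shuffled labels drive cross-validated accuracy to chance", {
  set.seed(42)
  n <- 300
  x <- matrix(rnorm(n * 3), n, 3)
  labels <- sample(rep(0:2, each = n / 3))
  subjects <- rep(sprintf("s%02d", 1:10), each = n / 10)
  d <- labeled_dataset(x, labels, subjects, "null")
  cv <- crossval_by_subject(d, "svm")
  expect_equal(length(cv$per_subject), 10)
  expect_lt(abs(cv$mean - 1 / 3), 0.06)
})

test_that("single-class training folds are skipped with a warning", {
  x <- matrix(rnorm(40), 20, 2)
  # subject "b" only performed score-0 trials, so fold "a" trains on a
  # single class
  labels <- c(rep(1:2, each = 5), rep(0, 10))
  subjects <- c(rep("a", 10), rep("b", 10))
  d <- labeled_dataset(x, labels, subjects, "toy")
  expect_warning(cv <- crossval_by_subject(d, "svm"), "single-class")
  expect_true(is.na(cv$per_subject[["a"]]))
})

test_that("training curve is seeded, bounded and improves with more instances", {
  d <- make_cluster_dataset(n_per_class = 12, sd = 2.5, sep = 5, seed = 14,
                            subjects = rep(paste0("s", 1:12), 3))
  tc1 <- training_curve(d, c(1, 5), reps = 25, seed = 3)
  tc2 <- training_curve(d, c(1, 5), reps = 25, seed = 3)
  expect_identical(tc1, tc2)
  expect_gte(tc2$accuracy[2], tc2$accuracy[1])
  expect_error(training_curve(d, 13, reps = 1), "fewer than")

  # m = all available, one rep: equals plain train/test (empty holdout ->
  # training accuracy)
  tc3 <- training_curve(d, 12, reps = 1, seed = 1)
  m <- train_svm(d)
  expect_equal(tc3$accuracy, accuracy(predict(m, d$x), d$labels))
})

test_that("models round-trip through the versioned JSON document", {
  d <- make_cluster_dataset(n_per_class = 5, sd = 0.01, sep = 10, seed = 15,
                            test_id = "elbow_flexion")
  ms <- list(elbow_flexion = train_svm(d),
             toy_bnn = train_bnn(d, seed = 2, epochs = 100))
  ms$toy_bnn$test_id <- "toy_bnn"
  path <- withr::local_tempfile(fileext = ".json")
  save_models(ms, path)
  back <- load_models(path)
  expect_named(back, names(ms))
  probe <- d$x + 0.001
  expect_equal(predict(back$elbow_flexion, probe),
               predict(ms$elbow_flexion, probe))
  expect_equal(predict(back$toy_bnn, probe), predict(ms$toy_bnn, probe))
})
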