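test_that("stratified folds partition the data with balanced class counts", {
  set.seed(51)
  y <- rep(c(0L, 1L), each = 50)[sample.int(100)]
  folds <- stratified_kfold(y, k = 5, seed = 52)
  expect_setequal(folds, 1:5)
  expect_equal(unname(table(folds)), rep(20L, 5), ignore_attr = TRUE)
  ones <- vapply(1:5, function(f) sum(y[folds == f] == 1), 0L)
  expect_equal(ones, rep(10L, 5))

  # nested sizes: outer training 80, inner training 64
  outer_train <- sum(folds != 1)
  expect_equal(outer_train, 80)
  inner <- stratified_kfold(y[folds != 1], k = 5, seed = 53)
  expect_equal(sum(inner != 1), 64)

  # unbalanced class sizes still differ by at most one across folds
  y2 <- c(rep(0L, 83), rep(1L, 17))
  f2 <- stratified_kfold(y2, k = 5, seed = 54)
  per_fold_ones <- vapply(1:5, function(f) sum(y2[f2 == f] == 1), 0L)
  expect_lte(diff(range(per_fold_ones)), 1)
  expect_error(stratified_kfold(c(0L, 1L), k = 5), class = "invalid_argument")
})

test_that("fold measures reproduce the confusion-matrix formulas", {
  # (TN, FN, FP, TP) = (40, 5, 10, 45)
  y_true <- c(rep(0L, 50), rep(1L, 50))
  y_pred <- c(rep(0L, 40), rep(1L, 10), rep(0L, 5), rep(1L, 45))
  prob <- ifelse(y_pred == 1, 0.9, 0.1)
  m <- fold_measures(y_true, y_pred, prob)
  expect_equal(unname(m["accuracy"]), 0.85)
  expect_equal(unname(m["sensitivity"]), 0.9)
  expect_equal(unname(m["specificity"]), 0.8)
  expect_equal(unname(m["f1"]), 90 / 105)

  # perfect probabilistic prediction
  mp <- fold_measures(y_true, y_true, as.numeric(y_true))
  expect_equal(unname(mp["brier"]), 0)
  expect_equal(unname(mp["auc"]), 1)

  # single-class truth: sensitivity/AUC (and F1) not computable
  m0 <- fold_measures(rep(0L, 20), rep(0L, 20), rep(0.2, 20))
  expect_true(is.na(m0["sensitivity"]))
  expect_true(is.na(m0["auc"]))
  expect_true(is.na(m0["f1"]))
  expect_equal(unname(m0["specificity"]), 1)

  # true ones present but none predicted: F1 is zero by convention
  m1 <- fold_measures(c(rep(0L, 15), rep(1L, 5)), rep(0L, 20), rep(0.1, 20))
  expect_equal(unname(m1["f1"]), 0)
})

test_that("fold AUC equals the brute-force concordant-pair count", {
  set.seed(55)
  for (i in 1:20) {
    n <- sample(6:30, 1)
    y <- rbinom(n, 1, 0.5)
    if (length(unique(y)) < 2) next
    prob <- round(runif(n), 2) # rounding forces occasional ties
    pairs <- expand.grid(i = which(y == 0), j = which(y == 1))
    conc <- sum(prob[pairs$j] > prob[pairs$i]) + 0.5 * sum(prob[pairs$j] == prob[pairs$i])
    expect_equal(auc_rank(prob, y), conc / nrow(pairs))
  }
  expect_true(is.na(auc_rank(c(0.1, 0.9), c(1, 1))))
})

test_that("fold aggregation averages only the computable folds", {
  mk <- function(acc, sens) c(accuracy = acc, f1 = 0.5, sensitivity = sens,
                              specificity = 0.5, auc = 0.5, brier = 0.1)
  panels <- list(mk(0.8, 0.9), mk(0.9, NA), mk(0.85, 0.8), mk(0.8, 0.7),
                 mk(0.9, 0.6))
  agg <- aggregate_folds(panels)
  expect_equal(unname(agg["accuracy"]), 0.85)
  expect_equal(unname(agg["sensitivity"]), 0.75)
  all_na <- lapply(1:5, function(i) mk(0.5, NA))
  expect_true(is.na(aggregate_folds(all_na)["sensitivity"]))
  expect_error(aggregate_folds(list()), class = "invalid_argument")
})

test_that("the fallback learner predicts the training majority", {
  fb <- fallback_predict(c(rep(0L, 60), rep(1L, 40)), 10)
  expect_equal(fb$pred, rep(0L, 10))
  expect_equal(fb$prob, rep(0.4, 10))
  expect_equal(fallback_predict(rep(1L, 5), 3)$pred, rep(1L, 3))
  expect_equal(fallback_predict(c(0L, 1L), 2)$pred, rep(0L, 2)) # tie -> class 0
  # fallback accuracy equals the majority-class frequency of the test fold
  y_te <- c(rep(0L, 13), rep(1L, 7))
  m <- fold_measures(y_te, fallback_predict(c(0L, 0L, 1L), 20)$pred,
                     fallback_predict(c(0L, 0L, 1L), 20)$prob)
  expect_equal(unname(m["accuracy"]), mean(y_te == 0))
})

test_that("random search returns the best-scoring configuration deterministically", {
  d <- separable_dataset(n = 60, seed = 56)
  cl <- classifier_spec("knn", budget = 8)
  t1 <- tune_random_search(cl, d$x, d$y, seed = 57)
  t2 <- tune_random_search(cl, d$x, d$y, seed = 57)
  expect_identical(t1, t2)
  expect_equal(t1$accuracy, max(t1$scores, na.rm = TRUE))
  cl1 <- classifier_spec("rf", budget = 1)
  tb <- tune_random_search(cl1, d$x, d$y, seed = 58)
  expect_equal(nrow(tb$config), 1)
  expect_length(tb$scores, 1)
})

test_that("all classifiers separate an easy two-cluster problem", {
  d <- separable_dataset(n = 100, seed = 59)
  res <- benchmark_dataset(d, default_classifiers(budget = 10), seed = 60)
  expect_equal(nrow(res), 5)
  expect_true(all(res$accuracy >= 0.95))
  expect_true(all(res$n_fallback_folds == 0))
})

test_that("a failing classifier falls back to the majority-class panel", {
  d <- separable_dataset(n = 50, seed = 61)
  # a 'classifier' whose search space is valid but whose fit always errors:
  # simulate by monkey-patching via an impossible configuration path is not
  # available, so check the contract through tune_random_search directly
  broken <- structure(list(name = "knn", budget = 2), class = "classifier_spec")
  d_bad <- d
  d_bad$x <- matrix(NA_real_, nrow(d$x), 2) # NAs make every fit/predict fail
  res <- benchmark_dataset(list(x = d_bad$x, y = d$y),
                           list(broken), seed = 62)
  expect_equal(res$n_fallback_folds, 5L)
  # fallback panel: accuracy equals per-fold majority frequency (~0.5)
  expect_lt(abs(res$accuracy - 0.5), 0.15)
})

test_that("benchmarking is deterministic and shares folds across classifiers", {
  d <- separable_dataset(n = 60, seed = 63)
  cls <- default_classifiers(budget = 3)
  r1 <- benchmark_dataset(d, cls, seed = 64)
  r2 <- benchmark_dataset(d, cls, seed = 64)
  expect_identical(r1, r2)
  # shared folds: one outer assignment per call, identical for every
  # classifier, and a valid stratified partition
  folds <- attr(r1, "outer_folds")
  expect_setequal(folds, 1:5)
  expect_length(folds, length(d$y))
  r_knn <- benchmark_dataset(d, cls["knn"], seed = 64)
  expect_identical(attr(r_knn, "outer_folds"), folds)
})
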