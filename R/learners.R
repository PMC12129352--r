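#' Classifier specifications
#'
#' The benchmark compares five binary classifiers: ridge and LASSO logistic
#' regression, a radial-kernel support vector machine, k-nearest neighbors
#' and a random forest. Each specification carries a random-search space and
#' a tuning budget (number of configurations evaluated by inner
#' cross-validation, default 100).
#'
#' Search spaces:
#' \describe{
#'   \item{ridge/lasso}{penalty `lambda` log-uniform on \[1e-4, 1e2\];}
#'   \item{svm}{cost and RBF kernel width `gamma` log-uniform on
#'     \[2^-10, 2^10\];}
#'   \item{knn}{`k` uniform on the integers 1..50 (clamped to the training
#'     size);}
#'   \item{rf}{500 trees; `mtry` fraction uniform on (0, 1\], minimum node
#'     size uniform on 1..10, sample fraction uniform on \[0.5, 1\].}
#' }
#'
#' @param name one of `"ridge"`, `"lasso"`, `"svm"`, `"knn"`, `"rf"`.
#' @param budget random-search budget (>= 1).
#' @return an object of class `classifier_spec`.
#' @export
classifier_spec <- function(name = c("ridge", "lasso", "svm", "knn", "rf"),
                            budget = 100) {
  name <- match.arg(name)
  if (budget < 1) stop_classed("invalid_argument", "budget must be >= 1")
  structure(list(name = name, budget = as.integer(budget)),
            class = "classifier_spec")
}

#' The default panel of five classifiers
#' @param budget shared random-search budget.
#' @return named list of [classifier_spec()] objects.
#' @export
default_classifiers <- function(budget = 100) {
  names_ <- c("ridge", "lasso", "svm", "knn", "rf")
  out <- lapply(names_, classifier_spec, budget = budget)
  names(out) <- names_
  out
}

#' Sample random-search configurations for a classifier
#' @noRd
sample_configs <- function(classifier, budget = classifier$budget) {
  switch(classifier$name,
    ridge = ,
    lasso = data.frame(lambda = 10^stats::runif(budget, -4, 2)),
    svm = data.frame(cost = 2^stats::runif(budget, -10, 10),
                     gamma = 2^stats::runif(budget, -10, 10)),
    knn = data.frame(k = sample.int(50, budget, replace = TRUE)),
    rf = data.frame(mtry_frac = stats::runif(budget),
                    min_node_size = sample.int(10, budget, replace = TRUE),
                    sample_fraction = stats::runif(budget, 0.5, 1)))
}

#' Fit a classifier on a training set with one configuration
#'
#' Returns an opaque model object for [predict_prob_learner()]. For the SVM,
#' predicted probabilities are obtained from a Platt-type logistic
#' calibration of the decision values, fitted on out-of-fold decision values
#' from a stratified internal cross-validation of the training data (the
#' radial SVM itself yields no probabilities).
#'
#' @noRd
fit_learner <- function(classifier, x, y, config, calibrate = TRUE) {
  x <- as.matrix(x)
  y <- as.integer(y)
  switch(classifier$name,
    ridge = ,
    lasso = {
      alpha <- if (classifier$name == "lasso") 1 else 0
      fit <- glmnet::glmnet(x, factor(y, levels = 0:1), family = "binomial",
                            alpha = alpha, lambda = config$lambda)
      list(kind = "glmnet", fit = fit, lambda = config$lambda)
    },
    svm = {
      fit <- e1071::svm(x, factor(y, levels = 0:1), kernel = "radial",
                        cost = config$cost, gamma = config$gamma,
                        scale = FALSE)
      platt <- if (calibrate) platt_calibration(classifier, x, y, config) else NULL
      list(kind = "svm", fit = fit, platt = platt)
    },
    knn = {
      k <- min(config$k, nrow(x))
      list(kind = "knn", x = x, y = y, k = k)
    },
    rf = {
      p <- ncol(x)
      fit <- randomForest::randomForest(
        x = x, y = factor(y, levels = 0:1), ntree = 500,
        mtry = max(1L, ceiling(config$mtry_frac * p)),
        nodesize = config$min_node_size,
        sampsize = max(2L, ceiling(config$sample_fraction * nrow(x))),
        replace = TRUE)
      list(kind = "rf", fit = fit)
    })
}

#' SVM decision values for class 1
#' @noRd
svm_decision <- function(fit, x) {
  dv <- attr(stats::predict(fit, x, decision.values = TRUE), "decision.values")
  # libsvm orients the decision value towards the first training class;
  # flip so larger values always mean class "1"
  if (colnames(dv)[1] == "0/1") drop(-dv[, 1]) else drop(dv[, 1])
}

#' Platt calibration of SVM decision values via internal CV
#' @noRd
platt_calibration <- function(classifier, x, y, config, folds = 3L) {
  assign_f <- tryCatch(stratified_kfold(y, k = folds),
                       error = function(e) NULL)
  dv <- rep(NA_real_, length(y))
  if (!is.null(assign_f)) {
    for (f in seq_len(folds)) {
      tr <- assign_f != f
      if (length(unique(y[tr])) < 2) next
      m <- tryCatch(
        e1071::svm(x[tr, , drop = FALSE], factor(y[tr], levels = 0:1),
                   kernel = "radial", cost = config$cost, gamma = config$gamma,
                   scale = FALSE),
        error = function(e) NULL)
      if (!is.null(m)) dv[!tr] <- svm_decision(m, x[!tr, , drop = FALSE])
    }
  }
  ok <- !is.na(dv)
  # fall back to in-sample decision values if the internal CV was unusable
  if (sum(ok) < 10 || length(unique(y[ok])) < 2) {
    fit_full <- e1071::svm(x, factor(y, levels = 0:1), kernel = "radial",
                           cost = config$cost, gamma = config$gamma,
                           scale = FALSE)
    dv <- svm_decision(fit_full, x)
    ok <- rep(TRUE, length(y))
  }
  suppressWarnings(
    stats::glm(y[ok] ~ dv[ok], family = stats::binomial())$coefficients
  )
}

#' Predicted class-1 probabilities from a fitted learner
#' @noRd
predict_prob_learner <- function(model, x) {
  x <- as.matrix(x)
  switch(model$kind,
    glmnet = drop(stats::predict(model$fit, x, s = model$lambda,
                                 type = "response")),
    svm = {
      dv <- svm_decision(model$fit, x)
      co <- model$platt
      if (is.null(co) || any(is.na(co))) {
        as.numeric(dv > 0) # uncalibrated hard prediction as last resort
      } else {
        stats::plogis(co[1] + co[2] * dv)
      }
    },
    knn = {
      pred <- class::knn(model$x, x, factor(model$y, levels = 0:1),
                         k = model$k, prob = TRUE)
      win <- attr(pred, "prob")
      ifelse(pred == "1", win, 1 - win)
    },
    rf = unname(stats::predict(model$fit, x, type = "prob")[, "1"]))
}

#' Evaluate many configurations on one inner train/test split
#'
#' Returns a matrix of class-1 scores (test rows x configurations); tuning
#' only thresholds these at 0.5 for accuracy. Ridge and LASSO evaluate all
#' penalties from a single regularization path fit; the other learners are
#' refitted per configuration.
#' @noRd
eval_configs <- function(classifier, x_tr, y_tr, x_te, configs) {
  x_tr <- as.matrix(x_tr)
  x_te <- as.matrix(x_te)
  if (classifier$name %in% c("ridge", "lasso")) {
    alpha <- if (classifier$name == "lasso") 1 else 0
    lam <- sort(unique(configs$lambda), decreasing = TRUE)
    fit <- glmnet::glmnet(x_tr, factor(y_tr, levels = 0:1),
                          family = "binomial", alpha = alpha, lambda = lam)
    pr <- stats::predict(fit, x_te, s = configs$lambda, type = "response")
    return(matrix(pr, nrow = nrow(x_te)))
  }
  if (classifier$name == "svm") {
    out <- matrix(NA_real_, nrow(x_te), nrow(configs))
    for (b in seq_len(nrow(configs))) {
      m <- fit_learner(classifier, x_tr, y_tr, configs[b, , drop = FALSE],
                       calibrate = FALSE)
      pred <- stats::predict(m$fit, x_te)
      out[, b] <- as.numeric(pred == "1")
    }
    return(out)
  }
  out <- matrix(NA_real_, nrow(x_te), nrow(configs))
  for (b in seq_len(nrow(configs))) {
    m <- fit_learner(classifier, x_tr, y_tr, configs[b, , drop = FALSE])
    out[, b] <- predict_prob_learner(m, x_te)
  }
  out
}

#' Majority-class fallback learner
#'
#' Substituted whenever a classifier fails on an outer fold: every test
#' observation is predicted as the training-majority class, and the
#' predicted class-1 probability is the training class-1 frequency. An exact
#' 50/50 tie predicts class 0 (fixed convention).
#'
#' @param train_y binary training outcomes.
#' @param test_size number of test observations.
#' @return list with `pred` (0/1 vector) and `prob` (class-1 probabilities).
#' @export
fallback_predict <- function(train_y, test_size) {
  if (length(train_y) == 0)
    stop_classed("invalid_argument", "train_y must be non-empty")
  p1 <- mean(train_y == 1)
  majority <- if (p1 > 0.5) 1L else 0L
  list(pred = rep(majority, test_size), prob = rep(p1, test_size))
}
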