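#' Stratified k-fold assignment
#'
#' Indices are partitioned into `k` folds so that the per-fold counts of each
#' class differ by at most one: within each class the indices are shuffled
#' and dealt to the folds round-robin, with the starting fold rotated per
#' class so fold sizes stay balanced overall.
#'
#' @param y binary outcome vector.
#' @param k number of folds (default 5).
#' @param seed optional integer seed.
#' @return integer vector of fold labels in `1..k`, same length as `y`.
#' @export
stratified_kfold <- function(y, k = 5, seed = NULL) {
  n <- length(y)
  if (n < k) stop_classed("invalid_argument", "need at least k observations")
  set_seed_if(seed)
  folds <- integer(n)
  offset <- 0L
  for (cls in sort(unique(y))) {
    idx <- which(y == cls)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- ((offset + seq_along(idx) - 1L) %% k) + 1L
    offset <- offset + length(idx)
  }
  folds
}

#' Rank-statistic AUC
#'
#' Area under the ROC curve computed as the normalized Mann-Whitney
#' statistic: the proportion of (class-0, class-1) pairs in which the class-1
#' observation receives the larger predicted probability, counting ties as
#' one half. `NA` when only one class is present.
#'
#' @param prob predicted class-1 probabilities.
#' @param y true 0/1 outcomes.
#' @return AUC in \[0, 1\], or `NA`.
#' @export
auc_rank <- function(prob, y) {
  n1 <- sum(y == 1)
  n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(prob)
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

#' Performance measures for one test fold
#'
#' Computes accuracy, F1-score, sensitivity, specificity, AUC and the Brier
#' score from hard predictions and predicted probabilities. Degenerate folds
#' follow fixed rules: with no true ones, sensitivity, F1 and AUC are `NA`
#' (not computable); with no true zeros, specificity and AUC are `NA`; with
#' true ones present but no predicted ones, F1 is set to 0, the worst value.
#' `NA` values are dropped later by per-measure fold averaging.
#'
#' @param y_true 0/1 truth for the fold.
#' @param y_pred 0/1 hard predictions.
#' @param prob predicted class-1 probabilities.
#' @return named numeric vector with elements `accuracy`, `f1`,
#'   `sensitivity`, `specificity`, `auc`, `brier`.
#' @export
fold_measures <- function(y_true, y_pred, prob) {
  n <- length(y_true)
  tp <- sum(y_true == 1 & y_pred == 1)
  tn <- sum(y_true == 0 & y_pred == 0)
  fp <- sum(y_true == 0 & y_pred == 1)
  fn <- sum(y_true == 1 & y_pred == 0)
  has_ones <- (tp + fn) > 0
  has_zeros <- (tn + fp) > 0
  f1 <- if (!has_ones) NA_real_
        else if (tp + fp == 0) 0 # true ones exist but none predicted
        else 2 * tp / (2 * tp + fp + fn)
  c(accuracy = (tn + tp) / n,
    f1 = f1,
    sensitivity = if (has_ones) tp / (tp + fn) else NA_real_,
    specificity = if (has_zeros) tn / (fp + tn) else NA_real_,
    auc = auc_rank(prob, y_true),
    brier = mean((prob - y_true)^2))
}

#' Average measure panels across folds
#'
#' Per measure, the mean over the folds in which the measure is computable;
#' folds with `NA` (single-class truth etc.) are left out for that measure
#' only. Probabilities are never pooled across folds for the AUC.
#'
#' @param panels list of per-fold measure vectors from [fold_measures()].
#' @return one aggregated named measure vector (a measure that is `NA` in
#'   every fold stays `NA`).
#' @export
aggregate_folds <- function(panels) {
  if (length(panels) == 0)
    stop_classed("invalid_argument", "no fold panels to aggregate")
  m <- do.call(rbind, panels)
  out <- suppressWarnings(colMeans(m, na.rm = TRUE))
  out[is.nan(out)] <- NA_real_
  out
}

#' Random-search hyperparameter tuning by inner cross-validation
#'
#' Samples `budget` configurations uniformly from the classifier's search
#' space and evaluates each by stratified k-fold cross-validation accuracy
#' on the training data (hard predictions at the 0.5 threshold). Returns the
#' configuration with the highest mean inner accuracy; ties are broken in
#' favor of the first-evaluated configuration. A configuration that fails in
#' a fold receives no score for that fold; if every configuration fails
#' everywhere, a `tuning_error` is raised (callers fall back to the
#' majority-class learner for the outer fold).
#'
#' @param classifier a [classifier_spec()].
#' @param x,y training covariates and 0/1 outcomes.
#' @param k inner folds (default 5).
#' @param seed optional integer seed (configuration sampling and fold
#'   assignment).
#' @return list with `config` (1-row data.frame), `accuracy` (mean inner CV
#'   accuracy of the winner) and `scores` (per-configuration mean accuracy).
#' @export
tune_random_search <- function(classifier, x, y, k = 5, seed = NULL) {
  stopifnot(inherits(classifier, "classifier_spec"))
  set_seed_if(seed)
  configs <- sample_configs(classifier)
  folds <- stratified_kfold(y, k = k)
  acc <- matrix(NA_real_, k, nrow(configs))
  for (f in seq_len(k)) {
    te <- folds == f
    if (length(unique(y[!te])) < 2 || sum(te) == 0) next
    scores <- tryCatch(
      eval_configs(classifier, x[!te, , drop = FALSE], y[!te],
                   x[te, , drop = FALSE], configs),
      error = function(e) NULL)
    if (is.null(scores)) next
    acc[f, ] <- colMeans((scores > 0.5) == (y[te] == 1))
  }
  mean_acc <- suppressWarnings(colMeans(acc, na.rm = TRUE))
  if (all(is.nan(mean_acc)))
    stop_classed("tuning_error", "all configurations failed in tuning")
  best <- which.max(mean_acc) # first index wins ties
  list(config = configs[best, , drop = FALSE],
       accuracy = mean_acc[best], scores = mean_acc)
}

#' Benchmark the classifier panel on one labeled dataset
#'
#' Runs 5-fold nested stratified cross-validation: the outer folds estimate
#' performance, and within each outer training set a random search with
#' inner cross-validation (see [tune_random_search()]) picks the
#' hyperparameters before the final fit. All classifiers share the same
#' outer fold assignment. If tuning, fitting or predicting fails on an outer
#' fold, the majority-class fallback learner supplies that fold's
#' predictions and the fold is counted under `n_fallback_folds`; warnings
#' are counted but do not trigger the fallback.
#'
#' @param data a `labeled_dataset` (list with covariates `x` and outcomes
#'   `y`), e.g. from [sample_outcomes_with_redraw()].
#' @param classifiers list of [classifier_spec()] objects.
#' @param k folds for the outer and inner loops (default 5).
#' @param seed optional integer seed; folds, configuration sampling and any
#'   stochastic learner internals all derive from it.
#' @return a data.frame with one row per classifier: the six aggregated
#'   measures plus `n_fallback_folds` and `n_warnings`.
#' @export
benchmark_dataset <- function(data, classifiers = default_classifiers(),
                              k = 5, seed = NULL) {
  x <- as.matrix(data$x)
  y <- as.integer(data$y)
  if (length(unique(y)) < 2)
    stop_classed("invalid_argument", "dataset must contain both classes")
  set_seed_if(seed)
  fold_seed <- sample.int(.Machine$integer.max, 1)
  outer <- stratified_kfold(y, k = k, seed = fold_seed)
  rows <- lapply(classifiers, function(cl) {
    panels <- vector("list", k)
    n_fallback <- 0L
    n_warn <- 0L
    for (f in seq_len(k)) {
      te <- outer == f
      x_tr <- x[!te, , drop = FALSE]
      y_tr <- y[!te]
      x_te <- x[te, , drop = FALSE]
      prob <- NULL
      withCallingHandlers(
        {
          prob <- tryCatch({
            tuned <- tune_random_search(cl, x_tr, y_tr, k = k)
            model <- fit_learner(cl, x_tr, y_tr, tuned$config)
            predict_prob_learner(model, x_te)
          }, error = function(e) NULL)
        },
        warning = function(w) {
          n_warn <<- n_warn + 1L
          invokeRestart("muffleWarning")
        })
      if (is.null(prob) || anyNA(prob)) {
        fb <- fallback_predict(y_tr, sum(te))
        prob <- fb$prob
        pred <- fb$pred
        n_fallback <- n_fallback + 1L
      } else {
        pred <- as.integer(prob > 0.5)
      }
      panels[[f]] <- fold_measures(y[te], pred, prob)
    }
    agg <- aggregate_folds(panels)
    data.frame(classifier = cl$name, t(agg),
               n_fallback_folds = n_fallback, n_warnings = n_warn,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "outer_folds") <- outer
  out
}
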