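#' Orientation of the six performance measures
#'
#' High values are good for all measures except the Brier score.
#' @return named character vector mapping measure to `"high_good"` /
#'   `"low_good"`.
#' @export
measure_orientation <- function() {
  c(accuracy = "high_good", f1 = "high_good", sensitivity = "high_good",
    specificity = "high_good", auc = "high_good", brier = "low_good")
}

#' Rank classifiers on one measure
#'
#' Rank 1 is always the best method, regardless of whether high or low
#' values of the measure indicate good performance. Exact ties are broken
#' uniformly at random (average ranks are not permitted for the Kendall
#' distance).
#'
#' @param values per-classifier measure values (no missing values; a missing
#'   value makes the ranking undefined and raises a `ranking_undefined`
#'   error).
#' @param orientation `"high_good"` or `"low_good"`.
#' @param seed optional integer seed for tie-breaking.
#' @return integer rank vector (permutation of `1..K`).
#' @export
rank_methods <- function(values, orientation = c("high_good", "low_good"),
                         seed = NULL) {
  orientation <- match.arg(orientation)
  if (anyNA(values))
    stop_classed("ranking_undefined",
                 "cannot rank methods with missing measure values")
  set_seed_if(seed)
  oriented <- if (orientation == "high_good") -values else values
  as.integer(rank(oriented, ties.method = "random"))
}

#' Relative error of a simulated measure value
#'
#' For the high-is-good measures the relative error of one minus the measure
#' is used, `((1 - m_hat) - (1 - m_true)) / (1 - m_true)`, which weighs
#' errors more heavily when the true performance is high. For the Brier
#' score the ordinary relative error `(m_hat - m_true) / m_true` applies.
#' Overestimating a high-good measure therefore gives a negative relative
#' error, overestimating the Brier score a positive one.
#'
#' @param m_hat simulated measure value.
#' @param m_true true measure value (from the Monte-Carlo oracle).
#' @param measure measure name, see [measure_orientation()].
#' @return the relative error; `NA` with a warning-free signal if the
#'   denominator vanishes (true value exactly 1, or exactly 0 for Brier).
#' @export
relative_error <- function(m_hat, m_true, measure) {
  orient <- measure_orientation()[[measure]]
  if (orient == "low_good") {
    if (m_true <= 0) return(NA_real_)
    (m_hat - m_true) / m_true
  } else {
    if (m_true >= 1) return(NA_real_)
    ((1 - m_hat) - (1 - m_true)) / (1 - m_true)
  }
}

#' Normalized Kendall distance between two rankings
#'
#' The number of adjacent transpositions needed to turn one ranking into the
#' other -- equivalently the number of discordant pairs -- divided by its
#' maximum `K (K - 1) / 2`. 0 means equal rankings, 1 means exactly reversed
#' rankings.
#'
#' @param r1,r2 rank vectors (permutations of `1..K`).
#' @return distance in \[0, 1\].
#' @export
kendall_distance <- function(r1, r2) {
  K <- length(r1)
  if (length(r2) != K)
    stop_classed("invalid_argument", "rankings must have equal length")
  if (!setequal(r1, seq_len(K)) || !setequal(r2, seq_len(K)))
    stop_classed("invalid_argument", "inputs must be permutations of 1..K")
  pairs <- utils::combn(K, 2)
  disc <- sum((r1[pairs[1, ]] - r1[pairs[2, ]]) *
              (r2[pairs[1, ]] - r2[pairs[2, ]]) < 0)
  disc / (K * (K - 1) / 2)
}

#' Acceptability interval from the reference relative errors
#'
#' The reference is the parametric simulation under the true scenario: its
#' relative errors for a given classifier, measure and dimensionality span
#' the range of results attainable by a well-specified study. The interval
#' is the closed span of the order statistics
#' `[x_(ceiling(0.025 n)), x_(floor(0.975 n))]`; for the standard 100
#' iterations this is `[x_(3), x_(97)]`, so that a reference of distinct
#' values scores exactly 95% acceptable against its own interval.
#'
#' @param reference_rel_errors numeric vector of reference relative errors
#'   (at least 10 values).
#' @return list with `lower`, `upper`, `n_reference`.
#' @export
acceptability_interval <- function(reference_rel_errors) {
  v <- reference_rel_errors[!is.na(reference_rel_errors)]
  n <- length(v)
  if (n < 10)
    stop_classed("insufficient_reference",
                 "need at least 10 reference relative errors")
  s <- sort(v)
  list(lower = s[ceiling(0.025 * n)], upper = s[floor(0.975 * n)],
       n_reference = n)
}

#' Proportion of acceptable simulation results
#'
#' Fraction of relative errors lying inside the closed acceptability
#' interval.
#'
#' @param rel_errors relative errors of the scenario under evaluation.
#' @param interval an [acceptability_interval()].
#' @return proportion in \[0, 1\]; `NA` for an empty list.
#' @export
proportion_acceptable <- function(rel_errors, interval) {
  v <- rel_errors[!is.na(rel_errors)]
  if (length(v) == 0) return(NA_real_)
  mean(v >= interval$lower & v <= interval$upper)
}

#' Monte-Carlo oracle for the true performances and ranking
#'
#' Draws `R` labeled datasets from the true DGP and OGM, benchmarks the full
#' classifier panel on each, and averages: the per-classifier,
#' per-measure mean is the true performance, and the ranking of those means
#' is the true ranking. Replicates whose outcome generation degenerates
#' (one class only after all redraws) are skipped and counted.
#'
#' @param dgp the true `dgp_spec`.
#' @param ogm the true (calibrated) `ogm_spec`.
#' @param classifiers list of [classifier_spec()] objects.
#' @param R number of replicates (full-scale default 500).
#' @param n per-dataset sample size.
#' @param seed integer seed; replicate seeds derive from it.
#' @param max_redraws redraw budget for degenerate outcomes.
#' @return list of class `true_performance` with `means` (classifier x
#'   measure matrix), `ranks` (same shape, integer), `R_effective`,
#'   `n_skipped`.
#' @export
estimate_true_performance <- function(dgp, ogm, classifiers = default_classifiers(),
                                      R = 500, n = 100, seed = 1,
                                      max_redraws = 50) {
  if (R < 2) stop_classed("invalid_argument", "R must be >= 2")
  acc <- NULL
  n_skipped <- 0L
  for (r in seq_len(R)) {
    gen <- function() {
      X <- rescale_minmax(sample_covariates(dgp, n))
      list(x = X, pi = predict_probabilities(X, ogm))
    }
    d <- tryCatch(
      sample_outcomes_with_redraw(gen, max_redraws = max_redraws,
                                  seed = derive_seed(seed, "oracle-data", r)),
      degenerate_outcome_error = function(e) NULL,
      degenerate_column_error = function(e) NULL)
    if (is.null(d)) {
      n_skipped <- n_skipped + 1L
      next
    }
    res <- benchmark_dataset(d, classifiers,
                             seed = derive_seed(seed, "oracle-bench", r))
    m <- as.matrix(res[, names(measure_orientation())])
    rownames(m) <- res$classifier
    acc <- if (is.null(acc)) list(sum = ifelse(is.na(m), 0, m),
                                  cnt = !is.na(m))
           else list(sum = acc$sum + ifelse(is.na(m), 0, m),
                     cnt = acc$cnt + !is.na(m))
  }
  if (is.null(acc))
    stop_classed("degenerate_outcome_error", "all oracle replicates degenerated")
  means <- acc$sum / acc$cnt
  means[acc$cnt == 0] <- NA_real_
  ranks <- matrix(NA_integer_, nrow(means), ncol(means),
                  dimnames = dimnames(means))
  for (ms in colnames(means)) {
    ranks[, ms] <- rank_methods(means[, ms],
                                orientation = measure_orientation()[[ms]],
                                seed = derive_seed(seed, "oracle-ties", ms))
  }
  structure(list(means = means, ranks = ranks,
                 R_effective = R - n_skipped, n_skipped = n_skipped),
            class = "true_performance")
}

#' Per-iteration errors, relative errors and Kendall distances
#'
#' Takes the long benchmark results of one scenario (the per-iteration
#' data.frames from [benchmark_dataset()], stacked with an `iteration`
#' column) and the oracle, and computes per classifier x measure the
#' estimation errors and relative errors, and per measure the normalized
#' Kendall distance between the iteration's method ranking and the true
#' ranking. Iterations in which a measure is missing for some classifier are
#' excluded from that measure's ranking (and from its error lists for the
#' affected classifier only).
#'
#' @param results stacked benchmark results with columns `iteration`,
#'   `classifier` and the six measures.
#' @param truth a `true_performance` oracle.
#' @param seed seed for the rank tie-breaking stream (kept separate from the
#'   data stream).
#' @return list with `errors` (long data.frame: iteration, classifier,
#'   measure, value, error, rel_error) and `kendall` (long data.frame:
#'   iteration, measure, distance).
#' @export
score_scenario <- function(results, truth, seed = 1) {
  stopifnot(inherits(truth, "true_performance"))
  measures <- names(measure_orientation())
  err_rows <- list()
  ken_rows <- list()
  for (it in unique(results$iteration)) {
    sub <- results[results$iteration == it, ]
    for (ms in measures) {
      vals <- sub[[ms]][match(rownames(truth$means), sub$classifier)]
      m_true <- truth$means[, ms]
      rel <- mapply(function(v, mt) {
        if (is.na(v) || is.na(mt)) NA_real_ else relative_error(v, mt, ms)
      }, vals, m_true)
      err_rows[[length(err_rows) + 1L]] <- data.frame(
        iteration = it, classifier = rownames(truth$means), measure = ms,
        value = vals, error = vals - m_true, rel_error = rel,
        stringsAsFactors = FALSE)
      if (!anyNA(vals)) {
        sim_rank <- rank_methods(vals, measure_orientation()[[ms]],
                                 seed = derive_seed(seed, "ties", it, ms))
        ken_rows[[length(ken_rows) + 1L]] <- data.frame(
          iteration = it, measure = ms,
          distance = kendall_distance(sim_rank, truth$ranks[, ms]),
          stringsAsFactors = FALSE)
      }
    }
  }
  list(errors = do.call(rbind, err_rows),
       kendall = if (length(ken_rows)) do.call(rbind, ken_rows) else NULL)
}

#' Summarize scenarios against the parametric-true reference
#'
#' Builds the acceptability intervals from the reference scenario's relative
#' errors (parametric simulation under the true scenario) and scores every
#' scenario: mean error, mean relative error, median Kendall distance and
#' the proportion of acceptable iterations, per scenario x classifier x
#' measure.
#'
#' @param scored named list of [score_scenario()] outputs, one per scenario
#'   id.
#' @param reference_id the scenario id serving as reference.
#' @return data.frame with columns `scenario_id`, `classifier`, `measure`,
#'   `mean_error`, `mean_rel_error`, `median_kendall`, `prop_acceptable`,
#'   `n_valid_iterations`.
#' @export
summarize_scenarios <- function(scored, reference_id) {
  if (!reference_id %in% names(scored))
    stop_classed("invalid_argument",
                 sprintf("reference scenario '%s' not found", reference_id))
  ref <- scored[[reference_id]]$errors
  intervals <- list()
  for (cl in unique(ref$classifier)) {
    for (ms in unique(ref$measure)) {
      key <- paste(cl, ms, sep = ".")
      re <- ref$rel_error[ref$classifier == cl & ref$measure == ms]
      intervals[[key]] <- if (sum(!is.na(re)) >= 10)
        acceptability_interval(re) else NULL
    }
  }
  rows <- list()
  for (sid in names(scored)) {
    err <- scored[[sid]]$errors
    ken <- scored[[sid]]$kendall
    for (cl in unique(err$classifier)) {
      for (ms in unique(err$measure)) {
        sel <- err$classifier == cl & err$measure == ms
        re <- err$rel_error[sel]
        iv <- intervals[[paste(cl, ms, sep = ".")]]
        kd <- if (!is.null(ken)) ken$distance[ken$measure == ms] else NA_real_
        rows[[length(rows) + 1L]] <- data.frame(
          scenario_id = sid,
          sim_type = if (grepl("_plasm_", sid)) "plasmode" else "parametric",
          classifier = cl, measure = ms,
          mean_error = mean(err$error[sel], na.rm = TRUE),
          mean_rel_error = mean(re, na.rm = TRUE),
          median_kendall = stats::median(kd, na.rm = TRUE),
          prop_acceptable = if (is.null(iv)) NA_real_
                            else proportion_acceptable(re, iv),
          n_valid_iterations = sum(!is.na(re)),
          stringsAsFactors = FALSE)
      }
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
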