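#!/usr/bin/env Rscript

# Step 3: score the simulation strategies against the frozen truth.
#
# Reads the per-iteration benchmark results written by step 2 and the true
# performances written alongside them, recomputes relative errors, Kendall
# distances and proportions of acceptable results, and prints the headline
# comparison: how close each simulation strategy comes to the parametric
# study under the true scenario (the reference, acceptable 95% by design).

suppressPackageStartupMessages(library(plasmodebench))

master_seed <- 20260924
res_file <- "results/p2_results.csv"
true_file <- "results/p2_true_performance.csv"
if (!file.exists(res_file) || !file.exists(true_file))
  stop("run analysis/02_run_scenarios.R first")

results <- utils::read.csv(res_file, stringsAsFactors = FALSE)
tp <- utils::read.csv(true_file, stringsAsFactors = FALSE)
means <- as.matrix(tp[, names(measure_orientation())])
rownames(means) <- tp$classifier
ranks <- means
for (ms in colnames(means)) {
  ranks[, ms] <- rank_methods(means[, ms], measure_orientation()[[ms]],
                              seed = derive_seed(master_seed, "oracle-ties", ms))
}
truth <- structure(list(means = means, ranks = ranks,
                        R_effective = NA, n_skipped = NA),
                   class = "true_performance")

scored <- lapply(split(results, results$scenario_id), function(df) {
  score_scenario(df, truth, seed = derive_seed(master_seed, "score",
                                               df$scenario_id[1]))
})
summ <- summarize_scenarios(scored, "p2_param_true")
utils::write.csv(summ, "results/p2_evaluation.csv", row.names = FALSE)

overall <- stats::aggregate(
  cbind(prop_acceptable, median_kendall) ~ scenario_id, summ, mean)
overall <- overall[order(-overall$prop_acceptable), ]
cat("Per-scenario means over classifiers x measures:\n\n")
print(transform(overall,
                prop_acceptable = round(prop_acceptable, 3),
                median_kendall = round(median_kendall, 3)),
      row.names = FALSE)

ref <- summ[summ$scenario_id == "p2_param_true", ]
cat(sprintf("\nreference self-acceptability (>= 0.95 by construction): %.3f\n",
            mean(ref$prop_acceptable)))
cat("full table: results/p2_evaluation.csv\n")
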