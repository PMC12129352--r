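#!/usr/bin/env Rscript

# Step 1: draw and freeze the "truth" of the meta-simulation study.
#
# For each dimensionality of the desk profile (p = 2 and p = 10) this draws
# the true data-generating process (mixed marginals + random correlation),
# draws and calibrates the true logistic outcome-generating model, and runs
# the Monte-Carlo oracle that defines the true classifier performances and
# the true method ranking. Everything is written to results/ as plain text;
# later steps reuse the same master seed, so the frozen truth is identical
# across scripts.

suppressPackageStartupMessages(library(plasmodebench))

master_seed <- 20260924
out_dir <- "results"
dir.create(out_dir, showWarnings = FALSE)

cfg <- study_config(profile = "desk", master_seed = master_seed,
                    calibration_n = 1e4)
cat("Desk profile:", cfg$iterations, "iterations, tuning budget", cfg$budget,
    ",", cfg$R_true, "oracle replicates, p in {",
    paste(cfg$p, collapse = ", "), "}\n\n")

for (p in cfg$p) {
  cat(sprintf("== p = %d ==\n", p))
  dgp <- build_dgp_spec(p, seed = derive_seed(master_seed, "dgp"),
                        concentration = cfg$concentration)
  cat("  roles:", paste(dgp$roles, collapse = ", "), "\n")
  ogm <- draw_coefficients(dgp, seed = derive_seed(master_seed, "ogm", p))
  ogm <- calibrate_intercept(ogm, dgp, calibration_n = cfg$calibration_n,
                             seed = derive_seed(master_seed, "calib", p))
  cat(sprintf("  calibrated intercept: %.3f (mean probability %.4f)\n",
              ogm$intercept, attr(ogm, "calibration_mean")))
  pre <- file.path(out_dir, sprintf("p%d", p))
  write_dgp_spec(dgp, paste0(pre, "_marginals.csv"),
                 paste0(pre, "_correlation.csv"))
  write_ogm_spec(ogm, paste0(pre, "_ogm.json"))

  truth <- estimate_true_performance(
    dgp, ogm, default_classifiers(cfg$budget), R = cfg$R_true, n = cfg$n,
    seed = derive_seed(master_seed, "oracle", p))
  cat(sprintf("  oracle: %d effective replicates (%d skipped)\n",
              truth$R_effective, truth$n_skipped))
  cat("  true performances (mean over replicates):\n")
  print(round(truth$means, 4))
  cat("  true ranking (1 = best):\n")
  print(truth$ranks)
  utils::write.csv(data.frame(classifier = rownames(truth$means),
                              round(truth$means, 6)),
                   paste0(pre, "_true_performance.csv"), row.names = FALSE)
  utils::write.csv(data.frame(classifier = rownames(truth$ranks), truth$ranks),
                   paste0(pre, "_true_ranks.csv"), row.names = FALSE)
  cat("\n")
}
cat("Frozen truth written under", out_dir, "\n")
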