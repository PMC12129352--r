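test_that("the scenario grid has the full misspecification layout per p", {
  cfg <- study_config(profile = "desk", master_seed = 5)
  grid <- enumerate_scenarios(cfg)
  expect_equal(nrow(grid), 2 * 38) # 22 parametric + 16 plasmode per p
  for (p in cfg$p) {
    sub <- grid[grid$p == p, ]
    expect_equal(sum(sub$sim_type == "parametric"), 22)
    expect_equal(sum(sub$sim_type == "plasmode"), 16)
    shifts <- sub$dev_param[sub$dev_kind == "shift"]
    expect_setequal(shifts, c(-0.5, -0.25, -0.125, 0.125, 0.25, 0.5))
    expect_setequal(sub$dev_param[sub$dev_kind == "scale"],
                    c(0.25, 0.5, 0.75, 1.33, 2, 4))
    expect_setequal(sub$dev_param[sub$dev_kind == "equicorrelation"],
                    c(-0.2, -0.1, 0, 0.1, 0.2))
  }
  expect_false(anyDuplicated(grid$scenario_id) > 0)
  # plasmode never misspecifies the DGP; parametric never resamples
  expect_true(all(grid$dev_kind[grid$sim_type == "plasmode"] == "none"))
  expect_true(all(is.na(grid$resampling[grid$sim_type == "parametric"])))
  expect_setequal(grid$ogm_factor, c(1, 0.5, 2, 0))
})

test_that("seed derivation is deterministic, distinct and in integer range", {
  s1 <- derive_seed(1, "dgp", 150)
  expect_identical(s1, derive_seed(1, "dgp", 150))
  expect_false(s1 == derive_seed(1, "dgp", 50))
  expect_false(s1 == derive_seed(2, "dgp", 150))
  many <- vapply(1:500, function(i) derive_seed(9, "x", i), 1L)
  expect_true(all(many >= 0 & many < 2^31 - 1))
  expect_gt(length(unique(many)), 495) # collisions essentially absent
})

test_that("DGP and OGM specifications round-trip through their text formats", {
  dir <- withr::local_tempdir()
  spec <- build_dgp_spec(10, seed = 81)
  mcsv <- file.path(dir, "marginals.csv")
  ccsv <- file.path(dir, "correlation.csv")
  write_dgp_spec(spec, mcsv, ccsv)
  back <- read_dgp_spec(mcsv, ccsv)
  expect_equal(back$marginals, spec$marginals, tolerance = 0)
  expect_equal(back$correlation, spec$correlation, tolerance = 0)
  expect_equal(dim(back$correlation), c(10, 10))
  # loading through build_dgp_spec subsets consistently
  spec2 <- build_dgp_spec(2, marginal_csv = mcsv, correlation_csv = ccsv)
  expect_equal(spec2$roles, c("normal", "bimodal"))

  # a hand-broken correlation file fails validation
  lines <- readLines(ccsv)
  parts <- strsplit(lines[1], ",")[[1]]
  parts[2] <- "0.9"
  lines[1] <- paste(parts, collapse = ",")
  writeLines(lines, ccsv)
  expect_error(read_dgp_spec(mcsv, ccsv), class = "validation_error")

  ogm <- calibrate_intercept(draw_coefficients(spec, seed = 82), spec,
                             calibration_n = 1e4, seed = 83)
  jpath <- file.path(dir, "ogm.json")
  write_ogm_spec(ogm, jpath)
  ogm2 <- read_ogm_spec(jpath)
  expect_identical(ogm2$intercept, ogm$intercept)
  expect_identical(ogm2$coefficients, ogm$coefficients)
  expect_identical(ogm2$null_model, ogm$null_model)
})

test_that("a miniature study runs end to end and reproduces itself", {
  cfg <- study_config(n = 60, p = 2, R_true = 3, iterations = 2, budget = 2,
                      calibration_n = 1e4, master_seed = 99, profile = "full")
  ids <- c("p2_param_true", "p2_plasm_none", "p2_param_scale0.25")
  dir <- withr::local_tempdir()
  out <- run_study(cfg, out_dir = dir, scenario_ids = ids)
  expect_named(out$p2$runs, ids, ignore.order = TRUE)
  ref <- out$p2$runs[["p2_param_true"]]$results
  expect_equal(sort(unique(ref$iteration)), 1:2)
  expect_equal(nrow(ref), 2 * 5)
  expect_true(all(!is.na(ref$accuracy)))
  expect_s3_class(out$p2$summary, "data.frame")
  expect_true(all(c("mean_error", "mean_rel_error", "median_kendall",
                    "prop_acceptable") %in% names(out$p2$summary)))
  expect_true(file.exists(file.path(dir, "p2_marginals.csv")))
  expect_true(file.exists(file.path(dir, "p2_results.csv")))
  expect_true(file.exists(file.path(dir, "p2_seed_manifest.json")))

  # bitwise reproducibility from the master seed
  out2 <- run_study(cfg, scenario_ids = ids)
  expect_identical(out2$p2$runs[["p2_param_true"]]$results, ref)
  expect_identical(out2$p2$truth$means, out$p2$truth$means)

  # scenario isolation: re-running a single scenario reproduces its rows
  solo <- run_scenario(out$scenarios[out$scenarios$scenario_id == "p2_plasm_none", ],
                       out$p2$dgp, out$p2$ogm, cfg,
                       default_classifiers(cfg$budget))
  expect_identical(solo$results, out$p2$runs[["p2_plasm_none"]]$results)
})
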