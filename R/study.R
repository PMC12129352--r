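#' Study configuration
#'
#' Collects the knobs of a full meta-simulation study. The full-scale
#' defaults are n = 100 observations per dataset, p in {2, 10, 50, 150}
#' variables, 500 oracle replicates, 100 iterations per scenario, 5-fold
#' nested cross-validation and a random-search budget of 100. The reduced
#' `profile = "desk"` (20 iterations, budget 10, 50 oracle replicates,
#' p in {2, 10}) runs a complete study on a single CPU in minutes and is the
#' profile exercised by the analysis scripts.
#'
#' @param n sample size of every generated dataset.
#' @param p vector of dimensionalities (subset of 2, 10, 50, 150).
#' @param R_true oracle replicates.
#' @param iterations iterations per scenario.
#' @param k folds for outer and inner cross-validation.
#' @param budget random-search budget.
#' @param max_redraws redraw budget for degenerate outcomes.
#' @param master_seed integer master seed; all other seeds derive from it.
#' @param concentration correlation-generator concentration.
#' @param calibration_n intercept-calibration sample size.
#' @param profile `"full"` or `"desk"`; `"desk"` overrides `iterations`,
#'   `budget`, `R_true` and `p` with the reduced values unless they are
#'   passed explicitly.
#' @return a list of class `study_config`.
#' @export
study_config <- function(n = 100, p = c(2, 10, 50, 150), R_true = 500,
                         iterations = 100, k = 5, budget = 100,
                         max_redraws = 50, master_seed = 1,
                         concentration = 50, calibration_n = 1e5,
                         profile = c("full", "desk")) {
  profile <- match.arg(profile)
  if (profile == "desk") {
    if (missing(iterations)) iterations <- 20
    if (missing(budget)) budget <- 10
    if (missing(R_true)) R_true <- 50
    if (missing(p)) p <- c(2, 10)
  }
  stopifnot(n > 0, iterations > 0, k > 1, budget > 0, R_true > 1)
  lapply(p, dgp_role_counts) # validates supported p
  structure(list(n = n, p = p, R_true = R_true, iterations = iterations,
                 k = k, budget = budget, max_redraws = max_redraws,
                 master_seed = master_seed, concentration = concentration,
                 calibration_n = calibration_n, profile = profile),
            class = "study_config")
}

#' Enumerate all scenarios of a study
#'
#' Per dimensionality p the default grid has 38 scenarios: 22 parametric
#' (the true scenario, 6 shifts, 6 scales, 5 equicorrelations, the complete
#' standard-normal misspecification, and 3 OGM scalings with the true DGP)
#' and 16 Plasmode (4 resampling schemes x {true OGM, c = 0.5, c = 2,
#' c = 0}). Parametric scenarios never carry a resampling scheme; Plasmode
#' scenarios never carry a DGP deviation (the DGP is only misspecifiable
#' parametrically).
#'
#' @param config a [study_config()].
#' @return data.frame with columns `scenario_id`, `p`, `sim_type`,
#'   `dev_kind`, `dev_param`, `ogm_factor`, `resampling`.
#' @export
enumerate_scenarios <- function(config) {
  rows <- list()
  add <- function(p, sim_type, dev, ogm_factor, resampling) {
    dev_lab <- if (is.null(dev)) "true" else deviation_label(dev)
    ogm_lab <- if (ogm_factor == 1) "" else sprintf("_c%g", ogm_factor)
    mid <- if (sim_type == "parametric") dev_lab else resampling
    id <- sprintf("p%d_%s_%s%s", p, substr(sim_type, 1, 5), mid, ogm_lab)
    rows[[length(rows) + 1L]] <<- data.frame(
      scenario_id = id, p = p, sim_type = sim_type,
      dev_kind = if (is.null(dev)) "none" else dev$kind,
      dev_param = dev_param_of(dev),
      ogm_factor = ogm_factor,
      resampling = if (is.null(resampling)) NA_character_ else resampling,
      stringsAsFactors = FALSE)
  }
  for (p in config$p) {
    add(p, "parametric", NULL, 1, NULL)
    for (dev in dgp_deviation_grid()) add(p, "parametric", dev, 1, NULL)
    for (cf in c(0.5, 2, 0)) add(p, "parametric", NULL, cf, NULL)
    for (scheme in names(resampling_grid())) {
      for (cf in c(1, 0.5, 2, 0)) add(p, "plasmode", NULL, cf, scheme)
    }
  }
  out <- do.call(rbind, rows)
  stopifnot(!anyDuplicated(out$scenario_id))
  out
}

#' @noRd
dev_param_of <- function(dev) {
  if (is.null(dev)) return(NA_real_)
  switch(dev$kind,
    shift = dev$delta, scale = dev$factor, equicorrelation = dev$rho,
    NA_real_)
}

#' @noRd
scenario_deviation <- function(scen) {
  switch(scen$dev_kind,
    none = dgp_deviation("none"),
    shift = dgp_deviation("shift", delta = scen$dev_param),
    scale = dgp_deviation("scale", factor = scen$dev_param),
    equicorrelation = dgp_deviation("equicorrelation", rho = scen$dev_param),
    standard_normal = dgp_deviation("standard_normal"))
}

#' @noRd
scenario_ogm <- function(ogm_true, ogm_factor) {
  if (ogm_factor == 0)
    return(ogm_spec(0, ogm_true$coefficients, null_model = TRUE))
  ogm_spec(ogm_true$intercept, ogm_true$coefficients,
           association_factor = ogm_factor)
}

#' Run all iterations of one scenario
#'
#' Parametric scenarios draw fresh covariates from the (possibly deviated)
#' DGP in every iteration; Plasmode scenarios resample from a base dataset
#' of size n that is drawn once from the true DGP for this scenario.
#' Outcomes come from the scenario OGM via the redraw rule; iterations whose
#' outcome generation degenerates even after all redraws are recorded and
#' skipped.
#'
#' @param scen one row of [enumerate_scenarios()] (as a list or 1-row
#'   data.frame).
#' @param dgp the frozen true `dgp_spec` for this p.
#' @param ogm_true the frozen calibrated true `ogm_spec` for this p.
#' @param config a [study_config()].
#' @param classifiers classifier panel (defaults to the study budget).
#' @return list with `results` (stacked [benchmark_dataset()] rows with an
#'   `iteration` column) and `n_degenerate`.
#' @export
run_scenario <- function(scen, dgp, ogm_true, config,
                         classifiers = default_classifiers(config$budget)) {
  scen <- as.list(scen)
  ogm <- scenario_ogm(ogm_true, scen$ogm_factor)
  n <- config$n
  seed0 <- derive_seed(config$master_seed, scen$scenario_id)
  if (scen$sim_type == "plasmode") {
    scheme <- resampling_grid()[[scen$resampling]]
    base <- local({
      for (try in 1:50) {
        b <- tryCatch(
          rescale_minmax(sample_covariates(dgp, n,
                                           seed = derive_seed(seed0, "base", try))),
          degenerate_column_error = function(e) NULL)
        if (!is.null(b)) return(b)
      }
      stop_classed("degenerate_column_error", "could not draw a base dataset")
    })
    make_gen <- function(it) {
      force(it)
      counter <- 0L
      function() {
        counter <<- counter + 1L
        X <- resample_covariates(base, scheme)
        list(x = X, pi = predict_probabilities(X, ogm))
      }
    }
  } else {
    dev <- scenario_deviation(scen)
    make_gen <- function(it) {
      force(it)
      function() {
        X <- rescale_minmax(sample_covariates(dgp, n))
        Xd <- apply_dgp_deviation(X, dev, spec = dgp, n = n)
        list(x = Xd, pi = predict_probabilities(Xd, ogm))
      }
    }
  }
  out <- list()
  n_degenerate <- 0L
  for (it in seq_len(config$iterations)) {
    d <- tryCatch(
      sample_outcomes_with_redraw(make_gen(it),
                                  max_redraws = config$max_redraws,
                                  seed = derive_seed(seed0, "data", it)),
      degenerate_outcome_error = function(e) NULL)
    if (is.null(d)) {
      n_degenerate <- n_degenerate + 1L
      next
    }
    res <- benchmark_dataset(d, classifiers, k = config$k,
                             seed = derive_seed(seed0, "bench", it))
    res$iteration <- it
    res$redraws_used <- d$redraws_used
    out[[length(out) + 1L]] <- res
  }
  list(results = if (length(out)) do.call(rbind, out) else NULL,
       n_degenerate = n_degenerate)
}

#' Run a complete study
#'
#' Per dimensionality p: (1) draw and freeze the true DGP and the calibrated
#' true OGM; (2) estimate the true performances and ranking with the
#' Monte-Carlo oracle; (3) run every scenario; (4) score all scenarios
#' against the parametric-true reference and summarize. When `out_dir` is
#' given, the frozen specs (marginal/correlation CSV, OGM JSON), long
#' results, per-scenario scores, summary tables and a seed manifest are
#' written there as plain text.
#'
#' @param config a [study_config()].
#' @param out_dir optional output directory.
#' @param scenario_ids optional character vector restricting which scenarios
#'   run (the parametric-true reference per p is always included).
#' @return named list per p with elements `dgp`, `ogm`, `truth`, `runs`,
#'   `scored`, `summary`, plus `scenarios` (the full grid) at the top level.
#' @export
run_study <- function(config, out_dir = NULL, scenario_ids = NULL) {
  grid <- enumerate_scenarios(config)
  out <- list(scenarios = grid)
  for (p in config$p) {
    pk <- sprintf("p%d", p)
    dgp <- build_dgp_spec(p, seed = derive_seed(config$master_seed, "dgp"),
                          concentration = config$concentration)
    ogm <- draw_coefficients(dgp, seed = derive_seed(config$master_seed, "ogm", p))
    ogm <- calibrate_intercept(ogm, dgp, calibration_n = config$calibration_n,
                               seed = derive_seed(config$master_seed, "calib", p))
    classifiers <- default_classifiers(config$budget)
    truth <- estimate_true_performance(
      dgp, ogm, classifiers, R = config$R_true, n = config$n,
      seed = derive_seed(config$master_seed, "oracle", p),
      max_redraws = config$max_redraws)
    ref_id <- sprintf("p%d_param_true", p)
    sel <- grid[grid$p == p, ]
    if (!is.null(scenario_ids))
      sel <- sel[sel$scenario_id %in% c(scenario_ids, ref_id), ]
    runs <- list()
    scored <- list()
    for (i in seq_len(nrow(sel))) {
      scen <- sel[i, ]
      run <- run_scenario(scen, dgp, ogm, config, classifiers)
      runs[[scen$scenario_id]] <- run
      if (!is.null(run$results))
        scored[[scen$scenario_id]] <- score_scenario(
          run$results, truth,
          seed = derive_seed(config$master_seed, "score", scen$scenario_id))
    }
    summary_df <- if (ref_id %in% names(scored))
      summarize_scenarios(scored, ref_id) else NULL
    out[[pk]] <- list(dgp = dgp, ogm = ogm, truth = truth, runs = runs,
                      scored = scored, summary = summary_df)
    if (!is.null(out_dir)) write_study_outputs(out[[pk]], p, config, out_dir)
  }
  out
}

#' @noRd
write_study_outputs <- function(res_p, p, config, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  pre <- file.path(out_dir, sprintf("p%d", p))
  write_dgp_spec(res_p$dgp, paste0(pre, "_marginals.csv"),
                 paste0(pre, "_correlation.csv"))
  write_ogm_spec(res_p$ogm, paste0(pre, "_ogm.json"))
  utils::write.csv(data.frame(res_p$truth$means,
                              classifier = rownames(res_p$truth$means)),
                   paste0(pre, "_true_performance.csv"), row.names = FALSE)
  wide <- do.call(rbind, lapply(names(res_p$runs), function(id) {
    r <- res_p$runs[[id]]$results
    if (is.null(r)) return(NULL)
    cbind(scenario_id = id, r)
  }))
  utils::write.csv(wide, paste0(pre, "_results.csv"), row.names = FALSE)
  utils::write.csv(results_long(wide), paste0(pre, "_results_long.csv"),
                   row.names = FALSE)
  if (!is.null(res_p$summary))
    utils::write.csv(res_p$summary, paste0(pre, "_summary.csv"),
                     row.names = FALSE)
  manifest <- list(master_seed = config$master_seed,
                   profile = config$profile,
                   seed_scheme = "derive_seed(master, scenario_id, {'data'|'bench'|'score'}, iteration)")
  jsonlite::write_json(manifest, paste0(pre, "_seed_manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(NULL)
}

#' Write an OGM specification as JSON
#'
#' Full-precision serialization of intercept, coefficients, association
#' factor and null flag; round-trips exactly through [read_ogm_spec()].
#'
#' @param ogm an `ogm_spec`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_ogm_spec <- function(ogm, path) {
  stopifnot(inherits(ogm, "ogm_spec"))
  # numbers written with 17 significant digits so the read-back is bitwise
  txt <- sprintf(
    '{"intercept": %s, "coefficients": [%s], "association_factor": %s, "null_model": %s}',
    format_full(ogm$intercept),
    paste(format_full(ogm$coefficients), collapse = ", "),
    format_full(ogm$association_factor),
    tolower(as.character(ogm$null_model)))
  writeLines(txt, path)
  invisible(path)
}

#' Read an OGM specification from JSON
#' @param path a file written by [write_ogm_spec()].
#' @return an `ogm_spec`.
#' @export
read_ogm_spec <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  ogm_spec(j$intercept, j$coefficients, j$association_factor, j$null_model)
}

#' Pivot stacked benchmark results to long format
#'
#' One row per scenario x iteration x classifier x measure, the layout used
#' for the persisted results tables.
#'
#' @param results stacked [benchmark_dataset()] rows with `scenario_id` and
#'   `iteration` columns.
#' @return data.frame with columns `scenario_id`, `sim_type`, `iteration`,
#'   `classifier`, `measure`, `value`, `n_fallback_folds`, `n_warnings`.
#' @export
results_long <- function(results) {
  measures <- names(measure_orientation())
  out <- do.call(rbind, lapply(measures, function(ms) {
    data.frame(scenario_id = results$scenario_id,
               sim_type = ifelse(grepl("_plasm_", results$scenario_id),
                                 "plasmode", "parametric"),
               iteration = results$iteration,
               classifier = results$classifier,
               measure = ms, value = results[[ms]],
               n_fallback_folds = results$n_fallback_folds,
               n_warnings = results$n_warnings,
               stringsAsFactors = FALSE)
  }))
  out[order(out$scenario_id, out$iteration, out$classifier), ]
}
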