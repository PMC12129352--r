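#' Logistic outcome-generating model (OGM) specification
#'
#' The OGM maps rescaled covariates to class-1 probabilities via
#' `plogis(b0 + x' beta)`, optionally followed by association scaling of the
#' log-odds by a factor `c` (see [scale_association()]). A null model has all
#' coefficients and intercept equal to zero, so every probability is 0.5.
#'
#' @param intercept intercept `b0`.
#' @param coefficients numeric coefficient vector `beta` (length p).
#' @param association_factor log-odds multiplier `c >= 0`, default 1.
#' @param null_model logical; `TRUE` forces the no-association null model.
#' @return an object of class `ogm_spec`.
#' @export
ogm_spec <- function(intercept, coefficients, association_factor = 1,
                     null_model = FALSE) {
  if (association_factor < 0)
    stop_classed("invalid_argument", "association_factor must be >= 0")
  if (null_model) {
    intercept <- 0
    coefficients <- rep(0, length(coefficients))
  }
  structure(list(intercept = as.numeric(intercept),
                 coefficients = as.numeric(coefficients),
                 association_factor = as.numeric(association_factor),
                 null_model = isTRUE(null_model)),
            class = "ogm_spec")
}

#' Draw true OGM coefficients for a DGP specification
#'
#' Per variable, the sign is +1 or -1 with probability one half each; the
#' magnitude is uniform on \[3, 8\] for normal, log-normal and contamination
#' variables and uniform on \[10, 15\] for bimodal variables. The larger
#' bimodal coefficients keep the two classes clearly separated as the
#' dimension grows. Because covariates are rescaled to \[0, 1\] before the
#' OGM is applied, odds ratios per increment of 0.1 (not 1) are the
#' realistic reading of these magnitudes; see [odds_ratio_per_increment()].
#' The intercept is left at 0 and should be set with
#' [calibrate_intercept()].
#'
#' @param spec a `dgp_spec` (supplies the role of each variable).
#' @param seed optional integer seed.
#' @return an `ogm_spec` with uncalibrated intercept 0.
#' @export
draw_coefficients <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "dgp_spec"))
  set_seed_if(seed)
  p <- spec$p
  signs <- sample(c(-1, 1), p, replace = TRUE)
  lo <- ifelse(spec$roles == "bimodal", 10, 3)
  hi <- ifelse(spec$roles == "bimodal", 15, 8)
  ogm_spec(0, signs * stats::runif(p, lo, hi))
}

#' Calibrate the OGM intercept for class balance
#'
#' The intercept is set so that the mean predicted probability over a fresh
#' calibration sample (rescaled covariates drawn from the DGP) equals the
#' target, i.e. the binary outcome is (nearly) balanced for the default
#' target of 0.5. The mean predicted probability is strictly increasing in
#' the intercept, so the root is found by monotone root-finding with
#' expanding brackets.
#'
#' @param ogm an `ogm_spec`.
#' @param spec the `dgp_spec` to sample calibration covariates from.
#' @param target target mean probability in (0, 1).
#' @param calibration_n calibration sample size (>= 1e4).
#' @param seed optional integer seed for the calibration sample.
#' @return the `ogm_spec` with calibrated intercept; the achieved mean
#'   probability on the calibration sample is within 1e-3 of `target`
#'   (attribute `calibration_mean`).
#' @export
calibrate_intercept <- function(ogm, spec, target = 0.5,
                                calibration_n = 1e5, seed = NULL) {
  stopifnot(inherits(ogm, "ogm_spec"), inherits(spec, "dgp_spec"))
  if (target <= 0 || target >= 1)
    stop_classed("invalid_argument", "target must lie in (0, 1)")
  if (calibration_n < 1e4)
    stop_classed("invalid_argument", "calibration_n must be >= 1e4")
  set_seed_if(seed)
  X <- rescale_minmax(sample_covariates(spec, calibration_n))
  eta <- drop(X %*% ogm$coefficients)
  f <- function(b0) mean(stats::plogis(b0 + eta)) - target
  lo <- -1
  hi <- 1
  for (i in 1:60) {
    if (f(lo) < 0 && f(hi) > 0) break
    lo <- lo * 2
    hi <- hi * 2
  }
  if (!(f(lo) < 0 && f(hi) > 0))
    stop_classed("calibration_error", "could not bracket the intercept root")
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-10)$root
  achieved <- f(root) + target
  if (abs(achieved - target) > 1e-3)
    stop_classed("calibration_error", "intercept calibration did not converge")
  out <- ogm_spec(root, ogm$coefficients, ogm$association_factor, ogm$null_model)
  attr(out, "calibration_mean") <- achieved
  out
}

#' Predicted class-1 probabilities under an OGM
#'
#' `pi_i = plogis(b0 + x_i' beta)`, followed by association scaling when the
#' OGM's factor differs from 1. The null model returns 0.5 everywhere.
#'
#' @param x covariate matrix (rescaled, possibly deviated).
#' @param ogm an `ogm_spec`.
#' @return numeric vector of probabilities strictly inside (0, 1).
#' @export
predict_probabilities <- function(x, ogm) {
  stopifnot(inherits(ogm, "ogm_spec"))
  x <- as.matrix(x)
  if (ncol(x) != length(ogm$coefficients))
    stop_classed("invalid_argument", sprintf(
      "x has %d columns but the OGM has %d coefficients",
      ncol(x), length(ogm$coefficients)))
  if (ogm$null_model) return(rep(0.5, nrow(x)))
  pi_hat <- stats::plogis(ogm$intercept + drop(x %*% ogm$coefficients))
  # keep probabilities strictly inside (0,1) so the log-odds stay finite
  pi_hat <- pmin(pmax(pi_hat, 1e-15), 1 - 1e-15)
  if (ogm$association_factor != 1)
    pi_hat <- scale_association(pi_hat, ogm$association_factor)
  pi_hat
}

#' Scale the association strength of predicted probabilities
#'
#' Transforms probabilities through `plogis(c * qlogis(pi))`: factors above 1
#' strengthen the covariate-outcome association (better separated classes),
#' factors below 1 weaken it, and `c = 0` removes it entirely (every
#' probability becomes 0.5). For a logistic OGM this is identical to
#' multiplying all coefficients, including the intercept, by `c`. Negative
#' factors merely swap the roles of the two classes, so only `c >= 0` is
#' exposed.
#'
#' @param pi_hat probabilities strictly inside (0, 1).
#' @param c_factor scaling factor `c >= 0`.
#' @return transformed probabilities.
#' @export
scale_association <- function(pi_hat, c_factor) {
  if (any(pi_hat <= 0) || any(pi_hat >= 1))
    stop_classed("invalid_argument",
                 "probabilities must be strictly inside (0, 1)")
  stats::plogis(c_factor * stats::qlogis(pi_hat))
}

#' Generate outcomes with the redraw rule
#'
#' Draws `y_i ~ Bernoulli(pi_i)` for a dataset produced by `generator`, a
#' closure returning `list(x = covariates, pi = probabilities)`. If the
#' outcome vector is all zeros or all ones, the whole dataset (covariates
#' included) is regenerated, up to `max_redraws` times; exhausting the budget
#' raises a `degenerate_outcome_error` and the scenario iteration is treated
#' as degenerate by callers. For Plasmode without resampling the generator
#' returns the same covariates every time, so effectively only the outcome
#' vector is redrawn.
#'
#' @param generator function of no arguments returning `list(x, pi)`.
#' @param max_redraws redraw budget (default 50).
#' @param seed optional integer seed.
#' @return a `labeled_dataset`: list with `x`, `y` (0/1 integer vector) and
#'   `redraws_used`.
#' @export
sample_outcomes_with_redraw <- function(generator, max_redraws = 50, seed = NULL) {
  set_seed_if(seed)
  for (attempt in 0:max_redraws) {
    # a constant-column draw is a pathological dataset too: spend a redraw
    d <- tryCatch(generator(), degenerate_column_error = function(e) NULL)
    if (is.null(d)) next
    y <- stats::rbinom(length(d$pi), 1L, d$pi)
    if (any(y == 0L) && any(y == 1L)) {
      return(structure(list(x = d$x, y = y, redraws_used = attempt),
                       class = "labeled_dataset"))
    }
  }
  stop_classed("degenerate_outcome_error", sprintf(
    "only one outcome class generated in all %d redraws", max_redraws))
}

#' Odds ratio for a small covariate increment
#'
#' Because covariates live on \[0, 1\], an increment of 0.1 is the realistic
#' unit for reading coefficients as odds ratios: `exp(beta * increment)`.
#'
#' @param beta coefficient.
#' @param increment covariate increment (default 0.1).
#' @return the odds ratio.
#' @examples
#' odds_ratio_per_increment(3) # 1.35
#' odds_ratio_per_increment(15) # 4.48
#' @export
odds_ratio_per_increment <- function(beta, increment = 0.1) {
  exp(beta * increment)
}
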