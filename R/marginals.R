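#' Marginal distribution specifications
#'
#' A covariate's marginal distribution belongs to one of four roles:
#' \describe{
#'   \item{normal}{a single Gaussian component;}
#'   \item{lognormal}{a log-normal, parameterised by the mean and variance of
#'     the underlying normal on the log scale (a skewed distribution);}
#'   \item{bimodal}{a two-component Gaussian mixture with well-separated
#'     means (a bimodal distribution);}
#'   \item{outlier}{a two-component contamination mixture: a dominant
#'     near-standard component plus a small-weight, high-variance component
#'     generating outliers.}
#' }
#' Components are stored as `(location, scale2)` pairs, i.e. mean and
#' variance on the relevant parameter scale (log scale for `lognormal`).
#'
#' @param role one of `"normal"`, `"lognormal"`, `"bimodal"`, `"outlier"`.
#' @param components numeric matrix with columns `location` and `scale2`, one
#'   row per mixture component.
#' @param weights mixture weights; nonnegative, summing to one. Length one
#'   for the non-mixture roles.
#' @return an object of class `marginal_spec`.
#' @export
marginal_spec <- function(role, components, weights) {
  role <- match.arg(role, c("normal", "lognormal", "bimodal", "outlier"))
  components <- matrix(as.numeric(components), ncol = 2,
                       dimnames = list(NULL, c("location", "scale2")))
  weights <- as.numeric(weights)
  n_comp <- nrow(components)
  expected <- if (role %in% c("normal", "lognormal")) 1L else 2L
  if (n_comp != expected)
    stop_classed("validation_error", sprintf(
      "role '%s' requires exactly %d component(s), got %d", role, expected, n_comp))
  if (length(weights) != n_comp)
    stop_classed("validation_error", "length(weights) must match number of components")
  if (any(weights < 0) || abs(sum(weights) - 1) > 1e-12)
    stop_classed("validation_error", "weights must be nonnegative and sum to 1")
  if (any(components[, "scale2"] <= 0))
    stop_classed("validation_error", "all component variances must be strictly positive")
  structure(list(role = role, components = components, weights = weights),
            class = "marginal_spec")
}

#' Hyper-distributions for drawing marginal parameters
#'
#' The true DGP draws the parameters of every marginal at random so that, in
#' expectation, standard-normal-like first components are obtained: the
#' expected location is 0 and the expected variance 1. The bimodal second
#' component has expected location 4; the contamination (outlier) second
#' component has expected variance 10.
#'
#' Defaults: locations are Normal with variance 0.25 around their expected
#' value; variances are Gamma with shape 4 and the stated mean (so they stay
#' well away from zero). Mixture weights are 0.5/0.5 for bimodal and 0.9/0.1
#' for the contamination model.
#'
#' @param loc_sd standard deviation of the Normal hyper-distribution for
#'   component locations.
#' @param var_shape Gamma shape for the variance hyper-distributions.
#' @param bimodal_loc2 expected location of the bimodal second component.
#' @param outlier_var2 expected variance of the contamination component.
#' @param bimodal_weights,outlier_weights mixture weights.
#' @return a list of hyperparameters used by [draw_marginal_params()].
#' @export
marginal_hyperparams <- function(loc_sd = 0.5, var_shape = 4,
                                 bimodal_loc2 = 4, outlier_var2 = 10,
                                 bimodal_weights = c(0.5, 0.5),
                                 outlier_weights = c(0.9, 0.1)) {
  list(loc_sd = loc_sd, var_shape = var_shape,
       bimodal_loc2 = bimodal_loc2, outlier_var2 = outlier_var2,
       bimodal_weights = bimodal_weights, outlier_weights = outlier_weights)
}

#' Draw the parameters of one marginal distribution
#'
#' @param role marginal role, see [marginal_spec()].
#' @param hyper hyper-distribution settings from [marginal_hyperparams()].
#' @param seed optional integer seed; `NULL` continues the current RNG stream.
#' @return a [marginal_spec()].
#' @examples
#' set.seed(1)
#' draw_marginal_params("bimodal")
#' @export
draw_marginal_params <- function(role, hyper = marginal_hyperparams(), seed = NULL) {
  role <- match.arg(role, c("normal", "lognormal", "bimodal", "outlier"))
  set_seed_if(seed)
  draw_comp <- function(loc_mean, var_mean) {
    c(location = stats::rnorm(1, loc_mean, hyper$loc_sd),
      scale2 = stats::rgamma(1, shape = hyper$var_shape,
                             rate = hyper$var_shape / var_mean))
  }
  switch(role,
    normal = ,
    lognormal = marginal_spec(role, rbind(draw_comp(0, 1)), 1),
    bimodal = marginal_spec(role,
      rbind(draw_comp(0, 1), draw_comp(hyper$bimodal_loc2, 1)),
      hyper$bimodal_weights),
    outlier = marginal_spec(role,
      rbind(draw_comp(0, 1), draw_comp(0, hyper$outlier_var2)),
      hyper$outlier_weights)
  )
}

#' Marginal CDF
#'
#' Closed form for all four roles (mixtures of normal CDFs; log-normal on the
#' original scale).
#' @param spec a [marginal_spec()].
#' @param x numeric vector of quantiles.
#' @return `P(X <= x)`.
#' @export
marginal_cdf <- function(spec, x) {
  stopifnot(inherits(spec, "marginal_spec"))
  sd_ <- sqrt(spec$components[, "scale2"])
  mu <- spec$components[, "location"]
  if (spec$role == "lognormal")
    return(stats::plnorm(x, meanlog = mu[1], sdlog = sd_[1]))
  out <- 0
  for (k in seq_along(spec$weights))
    out <- out + spec$weights[k] * stats::pnorm(x, mu[k], sd_[k])
  out
}

#' Marginal density
#' @param spec a [marginal_spec()].
#' @param x numeric vector.
#' @return density values.
#' @export
marginal_density <- function(spec, x) {
  stopifnot(inherits(spec, "marginal_spec"))
  sd_ <- sqrt(spec$components[, "scale2"])
  mu <- spec$components[, "location"]
  if (spec$role == "lognormal")
    return(stats::dlnorm(x, meanlog = mu[1], sdlog = sd_[1]))
  out <- 0
  for (k in seq_along(spec$weights))
    out <- out + spec$weights[k] * stats::dnorm(x, mu[k], sd_[k])
  out
}

#' Marginal quantile function
#'
#' Closed form for the normal and log-normal roles. For the mixture roles the
#' CDF is inverted numerically: a monotone grid inversion provides starting
#' values which are refined by Newton steps on the closed-form CDF/density.
#'
#' @param spec a [marginal_spec()].
#' @param u probabilities in (0, 1).
#' @return quantiles `F^{-1}(u)`.
#' @export
marginal_quantile <- function(spec, u) {
  stopifnot(inherits(spec, "marginal_spec"))
  mu <- spec$components[, "location"]
  sd_ <- sqrt(spec$components[, "scale2"])
  if (spec$role == "normal") return(stats::qnorm(u, mu[1], sd_[1]))
  if (spec$role == "lognormal") return(stats::qlnorm(u, meanlog = mu[1], sdlog = sd_[1]))
  # mixture roles: grid inversion + Newton polish
  lo <- min(stats::qnorm(1e-13, mu, sd_))
  hi <- max(stats::qnorm(1e-13, mu, sd_, lower.tail = FALSE))
  grid <- seq(lo, hi, length.out = 4096L)
  cdf <- marginal_cdf(spec, grid)
  # the grid CDF is nondecreasing; make it strictly increasing for approx()
  keep <- c(TRUE, diff(cdf) > 0)
  x <- stats::approx(cdf[keep], grid[keep], xout = u, rule = 2)$y
  for (i in 1:4) {
    f <- marginal_cdf(spec, x) - u
    d <- pmax(marginal_density(spec, x), 1e-300)
    x <- pmin(pmax(x - f / d, lo), hi)
  }
  x
}
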