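#' Variables per distribution class for each supported dimensionality
#'
#' The full data-generating process (DGP) specifies 150 marginals: 50 normal,
#' 50 log-normal, 25 bimodal and 25 contamination ("outlier") variables.
#' Lower-dimensional DGPs are first-k-per-role subsets so that results across
#' p stay comparable; p = 2 keeps the first normal and the first bimodal
#' variable.
#'
#' @param p number of variables; one of 2, 10, 50, 150.
#' @return named integer vector with counts for
#'   `normal`, `lognormal`, `bimodal`, `outlier`.
#' @export
dgp_role_counts <- function(p) {
  counts <- switch(as.character(p),
    "150" = c(normal = 50L, lognormal = 50L, bimodal = 25L, outlier = 25L),
    "50"  = c(normal = 15L, lognormal = 15L, bimodal = 10L, outlier = 10L),
    "10"  = c(normal = 3L,  lognormal = 3L,  bimodal = 2L,  outlier = 2L),
    "2"   = c(normal = 1L,  lognormal = 0L,  bimodal = 1L,  outlier = 0L),
    stop_classed("invalid_argument",
                 sprintf("unsupported p = %s; supported: 2, 10, 50, 150", p)))
  counts
}

#' Build (or load) a frozen true DGP specification
#'
#' Draws the parameters of all 150 marginals and the full 150 x 150 random
#' correlation matrix once, then keeps the subset corresponding to `p`. The
#' draw is frozen: the returned object records its seed, and re-building with
#' the same seed reproduces it exactly. Alternatively, previously exported
#' marginal and correlation tables can be loaded from CSV (see
#' [write_dgp_spec()] for the layout).
#'
#' @param p number of variables (2, 10, 50 or 150).
#' @param seed integer seed governing the parameter draw.
#' @param marginal_csv,correlation_csv optional paths to CSV files holding a
#'   previously drawn truth; both must be given together and describe at
#'   least `p` variables consistent with the role layout.
#' @param hyper marginal hyper-distributions, see [marginal_hyperparams()].
#' @param concentration concentration for [random_correlation_matrix()].
#' @return an object of class `dgp_spec` with elements `marginals` (list of
#'   [marginal_spec()]), `correlation`, `p`, `roles`, `seed`.
#' @export
build_dgp_spec <- function(p, seed = NULL, marginal_csv = NULL,
                           correlation_csv = NULL,
                           hyper = marginal_hyperparams(),
                           concentration = 50) {
  counts <- dgp_role_counts(p)
  if (!is.null(marginal_csv) || !is.null(correlation_csv)) {
    if (is.null(marginal_csv) || is.null(correlation_csv))
      stop_classed("invalid_argument",
                   "marginal_csv and correlation_csv must be given together")
    full <- read_dgp_spec(marginal_csv, correlation_csv)
  } else {
    set_seed_if(seed)
    full_counts <- dgp_role_counts(150)
    roles <- rep(names(full_counts), full_counts)
    marginals <- lapply(roles, draw_marginal_params, hyper = hyper)
    correlation <- random_correlation_matrix(150, concentration)
    full <- new_dgp_spec(marginals, roles, correlation, seed)
  }
  subset_dgp_spec(full, counts)
}

#' @noRd
new_dgp_spec <- function(marginals, roles, correlation, seed = NULL) {
  if (length(marginals) != nrow(correlation))
    stop_classed("validation_error",
                 "number of marginals must equal correlation dimension")
  validate_correlation(unclass(correlation))
  structure(list(marginals = marginals, roles = roles,
                 correlation = unclass(correlation),
                 p = length(marginals), seed = seed),
            class = "dgp_spec")
}

#' Take the first-k-per-role subset of a DGP specification
#' @noRd
subset_dgp_spec <- function(spec, counts) {
  have <- table(factor(spec$roles, levels = names(counts)))
  if (any(have < counts))
    stop_classed("validation_error", "spec does not contain enough variables per role")
  idx <- unlist(lapply(names(counts), function(r) {
    which(spec$roles == r)[seq_len(counts[[r]])]
  }), use.names = FALSE)
  idx <- sort(idx)
  new_dgp_spec(spec$marginals[idx], spec$roles[idx],
               spec$correlation[idx, idx, drop = FALSE], spec$seed)
}

#' Sample raw covariates from a DGP specification (NORTA)
#'
#' Correlated non-normal covariates are generated by the
#' normal-to-anything (Gaussian copula) mechanism: a latent multivariate
#' normal sample with the specified correlation matrix is mapped through the
#' standard-normal CDF and then through each marginal's quantile function.
#' The specified matrix is interpreted as the latent (copula-scale)
#' correlation.
#'
#' @param spec a `dgp_spec`.
#' @param n sample size (>= 1).
#' @param seed optional integer seed.
#' @return an `n x p` matrix of raw (not rescaled) covariates with attribute
#'   `rescaled = FALSE`; columns named `x1 ... xp`.
#' @export
sample_covariates <- function(spec, n, seed = NULL) {
  stopifnot(inherits(spec, "dgp_spec"))
  if (n < 1) stop_classed("invalid_argument", "n must be >= 1")
  validate_correlation(spec$correlation)
  set_seed_if(seed)
  U <- chol_factor(spec$correlation)
  Z <- matrix(stats::rnorm(n * spec$p), n, spec$p) %*% U
  X <- matrix(NA_real_, n, spec$p,
              dimnames = list(NULL, paste0("x", seq_len(spec$p))))
  for (j in seq_len(spec$p))
    X[, j] <- marginal_quantile(spec$marginals[[j]], stats::pnorm(Z[, j]))
  attr(X, "rescaled") <- FALSE
  X
}

#' Upper-triangular factor of a PSD correlation matrix
#'
#' Plain Cholesky when positive definite; eigenvalue-floored square root
#' otherwise (semi-definite matrices arise from nearest-PSD projections).
#' @noRd
chol_factor <- function(R) {
  ch <- tryCatch(chol(R), error = function(e) NULL)
  if (!is.null(ch)) return(ch)
  e <- eigen(R, symmetric = TRUE)
  t(e$vectors %*% diag(sqrt(pmax(e$values, 0)), nrow(R)))
}

#' Min-max rescale covariates to the unit interval
#'
#' Each column is transformed as `(x - min(x)) / (max(x) - min(x))`, so every
#' non-constant column attains minimum 0 and maximum 1. The per-column
#' minima and maxima are recorded as attributes. A constant column signals a
#' pathological draw and raises a `degenerate_column_error`, prompting the
#' caller to redraw the dataset.
#'
#' @param x covariate matrix.
#' @return the rescaled matrix, with attributes `rescaled = TRUE`,
#'   `col_min`, `col_max`.
#' @export
rescale_minmax <- function(x) {
  x <- as.matrix(x)
  cmin <- apply(x, 2, min)
  cmax <- apply(x, 2, max)
  if (any(cmax - cmin <= 0))
    stop_classed("degenerate_column_error",
                 sprintf("constant column(s): %s",
                         paste(which(cmax - cmin <= 0), collapse = ", ")))
  out <- sweep(sweep(x, 2, cmin, "-"), 2, cmax - cmin, "/")
  attr(out, "rescaled") <- TRUE
  attr(out, "col_min") <- cmin
  attr(out, "col_max") <- cmax
  out
}

#' DGP misspecifications
#'
#' Construct one controlled deviation of the data-generating process, as
#' applied in the parametric arm only:
#' \describe{
#'   \item{shift}{add `delta` to every rescaled observation;}
#'   \item{scale}{multiply every rescaled observation by `factor`;}
#'   \item{equicorrelation}{resample with all pairwise latent correlations
#'     fixed to `rho` (nearest-PSD-repaired when infeasible);}
#'   \item{standard_normal}{resample every variable as standard normal
#'     (then min-max rescaled like all other data);}
#'   \item{none}{the true DGP.}
#' }
#'
#' @param kind deviation kind.
#' @param delta shift amount (shift only).
#' @param factor scale factor > 0 (scale only).
#' @param rho common pairwise correlation in (-1, 1) (equicorrelation only).
#' @return an object of class `dgp_deviation`.
#' @export
dgp_deviation <- function(kind = c("none", "shift", "scale",
                                   "equicorrelation", "standard_normal"),
                          delta = NULL, factor = NULL, rho = NULL) {
  kind <- match.arg(kind)
  given <- c(shift = !is.null(delta), scale = !is.null(factor),
             equicorrelation = !is.null(rho))
  needed <- names(given)[given]
  if (kind %in% names(given)) {
    if (!given[[kind]] || length(needed) > 1)
      stop_classed("invalid_argument",
                   sprintf("deviation '%s' requires exactly its own parameter", kind))
  } else if (any(given)) {
    stop_classed("invalid_argument",
                 sprintf("deviation '%s' takes no parameter", kind))
  }
  if (kind == "scale" && factor <= 0)
    stop_classed("invalid_argument", "scale factor must be > 0")
  if (kind == "equicorrelation" && (rho <= -1 || rho >= 1))
    stop_classed("invalid_argument", "rho must lie in (-1, 1)")
  structure(list(kind = kind, delta = delta, factor = factor, rho = rho),
            class = "dgp_deviation")
}

#' The built-in misspecification grids
#'
#' Shift `delta` in {-0.5, -0.25, -0.125, 0.125, 0.25, 0.5}; scale `s` in
#' {0.25, 0.5, 0.75, 1.33, 2, 4}; equicorrelation `rho` in
#' {-0.2, -0.1, 0, 0.1, 0.2}; plus the complete standard-normal
#' misspecification.
#'
#' @return a list of `dgp_deviation` objects, named by a compact label.
#' @export
dgp_deviation_grid <- function() {
  devs <- c(
    lapply(c(-0.5, -0.25, -0.125, 0.125, 0.25, 0.5),
           function(d) dgp_deviation("shift", delta = d)),
    lapply(c(0.25, 0.5, 0.75, 1.33, 2, 4),
           function(s) dgp_deviation("scale", factor = s)),
    lapply(c(-0.2, -0.1, 0, 0.1, 0.2),
           function(r) dgp_deviation("equicorrelation", rho = r)),
    list(dgp_deviation("standard_normal"))
  )
  names(devs) <- vapply(devs, deviation_label, "")
  devs
}

#' @noRd
deviation_label <- function(dev) {
  switch(dev$kind,
    none = "true",
    shift = sprintf("shift%+g", dev$delta),
    scale = sprintf("scale%g", dev$factor),
    equicorrelation = sprintf("corr%+g", dev$rho),
    standard_normal = "stdnorm")
}

#' Apply a DGP misspecification to a rescaled covariate matrix
#'
#' Shift and scale transform the given data in place. The equicorrelation and
#' standard-normal deviations replace the data with a fresh sample (from the
#' modified DGP, or from N(0, I)), which is then min-max rescaled.
#'
#' @param x rescaled covariate matrix (from [rescale_minmax()]).
#' @param dev a [dgp_deviation()].
#' @param spec the true `dgp_spec` (needed for `equicorrelation`).
#' @param n sample size for the resampling deviations (defaults to `nrow(x)`).
#' @param seed optional integer seed for the resampling deviations.
#' @return a covariate matrix on the deviated scale.
#' @export
apply_dgp_deviation <- function(x, dev, spec = NULL, n = NULL, seed = NULL) {
  stopifnot(inherits(dev, "dgp_deviation"))
  if (is.null(n)) n <- nrow(x)
  switch(dev$kind,
    none = x,
    shift = {
      out <- x + dev$delta
      attr(out, "rescaled") <- FALSE
      out
    },
    scale = {
      out <- x * dev$factor
      attr(out, "rescaled") <- FALSE
      out
    },
    standard_normal = {
      set_seed_if(seed)
      p <- ncol(x)
      rescale_minmax(matrix(stats::rnorm(n * p), n, p,
                            dimnames = list(NULL, colnames(x))))
    },
    equicorrelation = {
      if (is.null(spec))
        stop_classed("invalid_argument", "equicorrelation deviation needs the DGP spec")
      set_seed_if(seed)
      p <- spec$p
      target <- matrix(dev$rho, p, p)
      diag(target) <- 1
      ev_min <- 1 + (p - 1) * dev$rho # smallest eigenvalue when rho < 0
      repaired <- if (ev_min < -1e-8 || min(eigen(target, symmetric = TRUE,
                                                  only.values = TRUE)$values) < -1e-8)
        nearest_psd_correlation(target) else validate_correlation(target)
      dev_spec <- new_dgp_spec(spec$marginals, spec$roles, repaired, spec$seed)
      rescale_minmax(sample_covariates(dev_spec, n))
    })
}

#' Export a DGP specification as plain-text tables
#'
#' Writes two files mirroring the supplementary layout of the frozen truth: a
#' marginal table with columns
#' `index, role, family, loc1, var1, loc2, var2, w1, w2` (empty cells for
#' absent second components) and a headerless comma-separated `p x p`
#' correlation matrix. All numbers are serialized at full precision so that a
#' read-back reproduces the specification bitwise.
#'
#' @param spec a `dgp_spec`.
#' @param marginal_csv,correlation_csv output paths.
#' @return invisibly, the two paths.
#' @export
write_dgp_spec <- function(spec, marginal_csv, correlation_csv) {
  stopifnot(inherits(spec, "dgp_spec"))
  rows <- lapply(seq_len(spec$p), function(j) {
    m <- spec$marginals[[j]]
    two <- nrow(m$components) == 2
    data.frame(index = j, role = m$role, family = "gaussian_mixture",
               loc1 = format_full(m$components[1, "location"]),
               var1 = format_full(m$components[1, "scale2"]),
               loc2 = if (two) format_full(m$components[2, "location"]) else "",
               var2 = if (two) format_full(m$components[2, "scale2"]) else "",
               w1 = format_full(m$weights[1]),
               w2 = if (two) format_full(m$weights[2]) else "",
               stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), marginal_csv, row.names = FALSE,
                   quote = FALSE)
  corr_txt <- apply(spec$correlation, 1, function(r)
    paste(format_full(r), collapse = ","))
  writeLines(corr_txt, correlation_csv)
  invisible(c(marginal_csv, correlation_csv))
}

#' Read a DGP specification from plain-text tables
#'
#' Inverse of [write_dgp_spec()]; validates the correlation matrix on read.
#'
#' @param marginal_csv,correlation_csv paths written by [write_dgp_spec()]
#'   (or hand-prepared files with the same layout).
#' @return a `dgp_spec`.
#' @examples
#' # a small synthetic example truth ships with the package
#' spec <- read_dgp_spec(
#'   system.file("extdata", "example_truth_marginals_synthetic.csv",
#'               package = "plasmodebench"),
#'   system.file("extdata", "example_truth_correlation_synthetic.csv",
#'               package = "plasmodebench"))
#' spec$roles
#' @export
read_dgp_spec <- function(marginal_csv, correlation_csv) {
  tab <- utils::read.csv(marginal_csv, stringsAsFactors = FALSE,
                         colClasses = c(role = "character"))
  required <- c("index", "role", "loc1", "var1", "loc2", "var2", "w1", "w2")
  if (!all(required %in% names(tab)))
    stop_classed("validation_error", sprintf(
      "marginal CSV lacks column(s): %s",
      paste(setdiff(required, names(tab)), collapse = ", ")))
  tab <- tab[order(tab$index), ]
  num <- function(v) suppressWarnings(as.numeric(v))
  marginals <- lapply(seq_len(nrow(tab)), function(i) {
    r <- tab[i, ]
    if (is.na(num(r$loc2)) || r$loc2 == "") {
      marginal_spec(r$role, rbind(c(num(r$loc1), num(r$var1))), num(r$w1))
    } else {
      marginal_spec(r$role,
                    rbind(c(num(r$loc1), num(r$var1)),
                          c(num(r$loc2), num(r$var2))),
                    c(num(r$w1), num(r$w2)))
    }
  })
  corr_rows <- strsplit(readLines(correlation_csv), ",", fixed = TRUE)
  corr <- do.call(rbind, lapply(corr_rows, function(r) num(r)))
  if (nrow(corr) != length(marginals) || ncol(corr) != length(marginals))
    stop_classed("validation_error",
                 "correlation CSV dimensions do not match the marginal table")
  new_dgp_spec(marginals, tab$role, validate_correlation(corr))
}
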