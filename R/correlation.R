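#' Validate a correlation matrix
#'
#' Checks symmetry (tolerance 1e-10), unit diagonal, off-diagonals in
#' \[-1, 1\] and positive semi-definiteness up to a small numerical tolerance
#' (smallest eigenvalue >= -1e-8).
#'
#' @param m numeric square matrix.
#' @return the matrix, invisibly, with class attribute `correlation_model`.
#' @export
validate_correlation <- function(m) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m))
    stop_classed("validation_error", "correlation matrix must be square")
  if (max(abs(m - t(m))) > 1e-10)
    stop_classed("validation_error", "correlation matrix must be symmetric")
  if (max(abs(diag(m) - 1)) > 1e-10)
    stop_classed("validation_error", "correlation matrix must have unit diagonal")
  if (any(m < -1 - 1e-12) || any(m > 1 + 1e-12))
    stop_classed("validation_error", "correlations must lie in [-1, 1]")
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop_classed("validation_error", sprintf(
      "correlation matrix is not positive semi-definite (min eigenvalue %.3g)",
      min(ev)))
  class(m) <- c("correlation_model", class(m))
  invisible(m)
}

#' Draw a random correlation matrix scattered around zero
#'
#' Uses the C-vine ("onion") construction: partial correlations are drawn
#' independently as `2 * Beta(a, a) - 1` with both shape parameters equal to
#' `concentration`, then converted to a valid correlation matrix by the
#' standard recursion. Large concentrations give partial correlations -- and
#' hence pairwise correlations -- tightly scattered around zero, matching the
#' weak dependence structure the framework targets; the result is always
#' exactly positive definite.
#'
#' @param p number of variables (>= 2).
#' @param concentration Beta shape parameter (> 0); the default 50 yields
#'   pairwise correlations with a standard deviation of roughly 0.1.
#' @param seed optional integer seed.
#' @return a `p x p` correlation matrix of class `correlation_model`.
#' @export
random_correlation_matrix <- function(p, concentration = 50, seed = NULL) {
  if (length(p) != 1 || p < 2)
    stop_classed("invalid_argument", "p must be a single integer >= 2")
  if (concentration <= 0)
    stop_classed("invalid_argument", "concentration must be > 0")
  set_seed_if(seed)
  p <- as.integer(p)
  P <- matrix(0, p, p) # partial correlations
  R <- diag(p)
  for (k in seq_len(p - 1)) {
    idx <- (k + 1):p
    P[k, idx] <- 2 * stats::rbeta(p - k, concentration, concentration) - 1
    rho <- P[k, idx]
    if (k > 1) {
      for (l in (k - 1):1)
        rho <- rho * sqrt((1 - P[l, idx]^2) * (1 - P[l, k]^2)) + P[l, idx] * P[l, k]
    }
    R[k, idx] <- rho
    R[idx, k] <- rho
  }
  validate_correlation(R)
}

#' Project a symmetric matrix onto the nearest correlation matrix
#'
#' Alternating projections with Dykstra correction (Higham's method) between
#' the positive semi-definite cone and the set of unit-diagonal symmetric
#' matrices. Needed for infeasible equicorrelation targets, e.g. all pairwise
#' correlations -0.2 at p = 150, where the smallest eigenvalue
#' `1 + (p - 1) * rho` of the raw target is negative.
#'
#' @param m symmetric matrix with unit diagonal (approximately).
#' @param tol convergence tolerance on successive iterates (Frobenius).
#' @param max_iter iteration cap.
#' @return the nearest correlation matrix (class `correlation_model`);
#'   idempotent on inputs that are already valid.
#' @export
nearest_psd_correlation <- function(m, tol = 1e-9, max_iter = 500) {
  m <- as.matrix(m)
  if (nrow(m) != ncol(m) || max(abs(m - t(m))) > 1e-8)
    stop_classed("invalid_argument", "input must be a symmetric square matrix")
  m <- (m + t(m)) / 2
  m[m > 1] <- 1
  m[m < -1] <- -1
  diag(m) <- 1
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) >= -1e-8) return(validate_correlation(m))
  Y <- m
  dS <- matrix(0, nrow(m), ncol(m))
  for (i in seq_len(max_iter)) {
    Rmat <- Y - dS
    e <- eigen(Rmat, symmetric = TRUE)
    pos <- pmax(e$values, 0)
    X <- e$vectors %*% (pos * t(e$vectors))
    X <- (X + t(X)) / 2
    dS <- X - Rmat
    Y_new <- X
    diag(Y_new) <- 1
    if (max(abs(Y_new - Y)) < tol) {
      Y <- Y_new
      break
    }
    Y <- Y_new
  }
  # final symmetrization and eigenvalue floor to guarantee PSD within tolerance
  Y <- (Y + t(Y)) / 2
  e <- eigen(Y, symmetric = TRUE)
  if (min(e$values) < 0) {
    pos <- pmax(e$values, 1e-12)
    Y <- e$vectors %*% (pos * t(e$vectors))
    d <- sqrt(diag(Y))
    Y <- Y / tcrossprod(d)
    Y <- (Y + t(Y)) / 2
  }
  diag(Y) <- 1
  validate_correlation(Y)
}
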