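test_that("role counts follow the per-dimension layout", {
  expect_equal(unname(dgp_role_counts(150)), c(50L, 50L, 25L, 25L))
  expect_equal(unname(dgp_role_counts(50)), c(15L, 15L, 10L, 10L))
  expect_equal(unname(dgp_role_counts(10)), c(3L, 3L, 2L, 2L))
  expect_equal(unname(dgp_role_counts(2)), c(1L, 0L, 1L, 0L))
  expect_error(dgp_role_counts(7), class = "invalid_argument")

  spec150 <- build_dgp_spec(150, seed = 1)
  expect_equal(unname(table(factor(spec150$roles,
                                   c("normal", "lognormal", "bimodal", "outlier")))),
               c(50L, 50L, 25L, 25L), ignore_attr = TRUE)
  spec2 <- build_dgp_spec(2, seed = 1)
  expect_equal(spec2$roles, c("normal", "bimodal"))
})

test_that("lower-dimensional specs are first-k-per-role subsets of the parent", {
  spec150 <- build_dgp_spec(150, seed = 7)
  spec10 <- build_dgp_spec(10, seed = 7)
  idx <- c(1:3, 51:53, 101:102, 126:127) # first 3+3+2+2 per role block
  expect_identical(spec10$marginals, spec150$marginals[idx])
  expect_identical(spec10$correlation, spec150$correlation[idx, idx])
})

test_that("random correlation matrices are valid and scattered around zero", {
  off_means <- vapply(1:20, function(s) {
    R <- random_correlation_matrix(50, seed = s)
    expect_equal(unname(diag(R)), rep(1, 50))
    expect_gte(min(eigen(R, symmetric = TRUE, only.values = TRUE)$values), -1e-8)
    mean(R[upper.tri(R)])
  }, 0)
  expect_true(all(off_means > -0.05 & off_means < 0.05))
  expect_error(random_correlation_matrix(1), class = "invalid_argument")
})

test_that("NORTA sampling reproduces marginals and correlations", {
  nm <- single_marginal_dgp(marginal_spec("normal", rbind(c(0, 1)), 1))
  x <- sample_covariates(nm, 1e5, seed = 3)
  expect_lt(abs(mean(x)), 0.02)
  expect_lt(abs(stats::var(drop(x)) - 1), 0.05)

  ln <- single_marginal_dgp(marginal_spec("lognormal", rbind(c(0, 1)), 1))
  xl <- sample_covariates(ln, 1e5, seed = 4)
  expect_lt(abs(stats::median(xl) - 1), 0.03)

  two <- two_normal_dgp(0.3)
  xt <- sample_covariates(two, 1e5, seed = 5)
  expect_lt(abs(stats::cor(xt)[1, 2] - 0.3), 0.02)
})

test_that("sampling is deterministic under a fixed seed", {
  spec <- build_dgp_spec(10, seed = 11)
  spec2 <- build_dgp_spec(10, seed = 11)
  expect_identical(spec, spec2)
  x1 <- sample_covariates(spec, 200, seed = 12)
  x2 <- sample_covariates(spec, 200, seed = 12)
  expect_identical(x1, x2)
})

test_that("min-max rescaling maps columns onto [0, 1] and is idempotent", {
  expect_equal(drop(rescale_minmax(cbind(c(2, 4, 6)))), c(0, 0.5, 1),
               ignore_attr = TRUE)
  x01 <- cbind(c(0, 1, 0.25))
  expect_equal(drop(rescale_minmax(x01)), drop(x01), ignore_attr = TRUE)
  expect_error(rescale_minmax(cbind(c(5, 5, 5))),
               class = "degenerate_column_error")
  x <- matrix(stats::rnorm(60), 20, 3)
  once <- rescale_minmax(x)
  expect_identical(rescale_minmax(once)[, ], once[, ])
})

test_that("shift and scale deviations act elementwise and compose to identity", {
  x <- rescale_minmax(matrix(stats::runif(40), 20, 2))
  sh <- apply_dgp_deviation(x, dgp_deviation("shift", delta = 0.125))
  expect_equal(sh[1, 1], x[1, 1] + 0.125)
  back <- apply_dgp_deviation(sh, dgp_deviation("shift", delta = -0.125))
  expect_equal(unclass(back)[, ], unclass(x)[, ], tolerance = 1e-15)
  sc <- apply_dgp_deviation(x, dgp_deviation("scale", factor = 2))
  expect_equal(drop(sc[, 2]), drop(x[, 2] * 2))
  undone <- apply_dgp_deviation(sc, dgp_deviation("scale", factor = 0.5))
  expect_equal(unclass(undone)[, ], unclass(x)[, ], tolerance = 1e-12)
  expect_identical(apply_dgp_deviation(x, dgp_deviation("none")), x)
})

test_that("deviation constructor rejects mismatched parameters", {
  expect_error(dgp_deviation("shift"), class = "invalid_argument")
  expect_error(dgp_deviation("shift", delta = 0.1, factor = 2),
               class = "invalid_argument")
  expect_error(dgp_deviation("none", delta = 0.1), class = "invalid_argument")
  expect_error(dgp_deviation("scale", factor = -1), class = "invalid_argument")
  grid <- dgp_deviation_grid()
  expect_length(grid, 18) # 6 shift + 6 scale + 5 correlation + 1 distribution
})

test_that("infeasible equicorrelation targets are repaired before sampling", {
  p <- 150
  target <- matrix(-0.2, p, p)
  diag(target) <- 1
  # smallest eigenvalue of the raw target is 1 + (p-1)*rho < 0
  expect_lt(1 + (p - 1) * (-0.2), 0)
  repaired <- nearest_psd_correlation(target)
  expect_gte(min(eigen(repaired, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
  expect_equal(unname(diag(repaired)), rep(1, p))
  # independent oracle: Higham projection as implemented in Matrix::nearPD
  oracle <- as.matrix(Matrix::nearPD(target, corr = TRUE)$mat)
  d_ours <- norm(repaired - target, "F")
  d_oracle <- norm(oracle - target, "F")
  expect_lt(abs(d_ours - d_oracle), 1e-4)
})

test_that("nearest-correlation projection is idempotent on valid input", {
  R <- random_correlation_matrix(8, seed = 2)
  expect_equal(unclass(nearest_psd_correlation(R)), unclass(R), tolerance = 1e-8)
  m <- matrix(c(1, 1, 1, 1), 2, 2) # off-diagonal at the boundary
  out <- nearest_psd_correlation(m)
  expect_true(all(abs(out) <= 1 + 1e-12))
  expect_error(nearest_psd_correlation(matrix(c(1, 0.5, 0.1, 1), 2, 2)),
               class = "invalid_argument")
})

test_that("equicorrelation and standard-normal deviations resample and rescale", {
  spec <- build_dgp_spec(10, seed = 21)
  x <- rescale_minmax(sample_covariates(spec, 300, seed = 22))
  eq <- apply_dgp_deviation(x, dgp_deviation("equicorrelation", rho = 0.2),
                            spec = spec, seed = 23)
  expect_equal(dim(eq), dim(x))
  expect_equal(unname(apply(eq, 2, min)), rep(0, 10))
  expect_equal(unname(apply(eq, 2, max)), rep(1, 10))
  sn <- apply_dgp_deviation(x, dgp_deviation("standard_normal"), seed = 24)
  expect_equal(unname(apply(sn, 2, range)), matrix(rep(c(0, 1), 10), 2))
})
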