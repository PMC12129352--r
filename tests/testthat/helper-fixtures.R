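# Shared test fixtures, built in code at test time.

# A one-variable DGP around a single marginal, for marginal-fidelity checks.
single_marginal_dgp <- function(marginal, role = marginal$role) {
  plasmodebench:::new_dgp_spec(list(marginal), role,
                               matrix(1, 1, 1, dimnames = NULL))
}

two_normal_dgp <- function(rho) {
  m <- marginal_spec("normal", rbind(c(0, 1)), 1)
  plasmodebench:::new_dgp_spec(list(m, m), c("normal", "normal"),
                               matrix(c(1, rho, rho, 1), 2, 2))
}

# Brute-force Kendall distance: count adjacent swaps needed by bubble sort to
# transform ranking r1 into r2 (equivalently, sort r2 by the order of r1).
kendall_bruteforce <- function(r1, r2) {
  # express r2 in the coordinate system where r1 is the identity
  v <- r2[order(r1)]
  swaps <- 0
  repeat {
    done <- TRUE
    for (i in seq_len(length(v) - 1)) {
      if (v[i] > v[i + 1]) {
        tmp <- v[i]; v[i] <- v[i + 1]; v[i + 1] <- tmp
        swaps <- swaps + 1
        done <- FALSE
      }
    }
    if (done) break
  }
  swaps / choose(length(r1), 2)
}

# A clearly separable two-cluster binary dataset.
separable_dataset <- function(n = 100, seed = 1) {
  set.seed(seed)
  y <- rep(0:1, each = n / 2)
  x <- cbind(x1 = y * 0.8 + stats::runif(n, 0, 0.15),
             x2 = y * 0.8 + stats::runif(n, 0, 0.15))
  idx <- sample.int(n)
  structure(list(x = x[idx, ], y = y[idx], redraws_used = 0L),
            class = "labeled_dataset")
}

# Small calibrated truth at p = 2, memoised across tests in one session.
cached_truth_p2 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      dgp <- build_dgp_spec(2, seed = 2024)
      ogm <- draw_coefficients(dgp, seed = 2025)
      ogm <- calibrate_intercept(ogm, dgp, calibration_n = 1e4, seed = 2026)
      cache <<- list(dgp = dgp, ogm = ogm)
    }
    cache
  }
})
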