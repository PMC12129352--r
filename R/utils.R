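#' Derive a child seed from a master seed and a key path
#'
#' Child seeds for every random decision (parameter draws, covariate sampling,
#' resampling, tuning, tie-breaking) are derived from a single master seed and
#' a human-readable key path, so that any scenario or iteration can be re-run
#' in isolation and reproduce its results bitwise.
#'
#' The scheme is a simple polynomial string hash over the concatenated keys,
#' reduced modulo 2^31 - 1, which keeps the result in the range of a valid R
#' integer seed.
#'
#' @param master integer master seed.
#' @param ... further keys (character or numeric), e.g. a scenario id and an
#'   iteration number.
#' @return a single integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(master, ...) {
  keys <- paste(c(as.character(master), vapply(list(...), as.character, "")),
                collapse = "/")
  h <- 0
  for (b in utf8ToInt(keys)) h <- (h * 31 + b) %% 2147483647
  as.integer(h)
}

#' Set the RNG seed if one is given
#'
#' Internal convention: all stochastic operations accept a `seed` argument;
#' `NULL` means "continue from the current RNG state".
#' @noRd
set_seed_if <- function(seed) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  invisible(NULL)
}

#' Signal a classed error condition
#' @noRd
stop_classed <- function(class, message, ...) {
  stop(structure(
    class = c(class, "plasmodebench_error", "error", "condition"),
    list(message = message, call = sys.call(-1), ...)
  ))
}

#' Numeric formatting that round-trips through text exactly
#' @noRd
format_full <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) "NA" else sprintf("%.17g", v)
  }, "")
}
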