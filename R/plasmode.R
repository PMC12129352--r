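#' Plasmode resampling schemes
#'
#' Plasmode covariate datasets are obtained by resampling rows of a fixed
#' base dataset (drawn once from the true DGP). Two families are supported,
#' each with resampling proportions 0.632 and 1:
#' \describe{
#'   \item{bootstrap}{m-out-of-n bootstrap: `m = round(proportion * n)` rows
#'     drawn with replacement;}
#'   \item{subsample}{`m` distinct rows drawn without replacement; a
#'     proportion of 1 means no resampling at all -- the full base dataset is
#'     used unchanged.}
#' }
#'
#' @param kind `"bootstrap"` or `"subsample"`.
#' @param proportion resampling proportion in (0, 1].
#' @return an object of class `resampling_scheme` with a compact `label`
#'   (`boot0.632`, `boot1`, `sub0.632`, `none`).
#' @export
resampling_scheme <- function(kind = c("bootstrap", "subsample"), proportion) {
  kind <- match.arg(kind)
  if (proportion <= 0 || proportion > 1)
    stop_classed("invalid_argument", "proportion must lie in (0, 1]")
  label <- if (kind == "subsample" && proportion == 1) "none"
           else sprintf("%s%g", ifelse(kind == "bootstrap", "boot", "sub"),
                        proportion)
  structure(list(kind = kind, proportion = proportion, label = label),
            class = "resampling_scheme")
}

#' The built-in grid of resampling schemes
#'
#' `{bootstrap, subsample} x {0.632, 1}`.
#' @return named list of [resampling_scheme()] objects.
#' @export
resampling_grid <- function() {
  schemes <- list(
    resampling_scheme("bootstrap", 0.632),
    resampling_scheme("bootstrap", 1),
    resampling_scheme("subsample", 0.632),
    resampling_scheme("subsample", 1)
  )
  names(schemes) <- vapply(schemes, `[[`, "", "label")
  schemes
}

#' Resample covariates from a Plasmode base dataset
#'
#' Every output row is one of the base rows; no new covariate values are
#' synthesized. Row order is randomized for actual resampling so that fold
#' assignment downstream is not tied to the base ordering; the no-resampling
#' scheme returns the base dataset unchanged (same rows, same order), so
#' repeated iterations differ only through the outcome noise.
#'
#' @param base rescaled covariate matrix with `n >= 2` rows.
#' @param scheme a [resampling_scheme()].
#' @param seed optional integer seed.
#' @return a covariate matrix with `m = round(proportion * n)` rows.
#' @export
resample_covariates <- function(base, scheme, seed = NULL) {
  stopifnot(inherits(scheme, "resampling_scheme"))
  n <- nrow(base)
  if (is.null(n) || n < 2)
    stop_classed("invalid_argument", "base dataset must have at least 2 rows")
  m <- round(scheme$proportion * n)
  if (m < 2)
    stop_classed("invalid_argument", "resampled size m must be >= 2")
  if (scheme$kind == "subsample" && scheme$proportion == 1) return(base)
  set_seed_if(seed)
  idx <- if (scheme$kind == "bootstrap") sample.int(n, m, replace = TRUE)
         else sample.int(n, m, replace = FALSE)
  out <- base[idx, , drop = FALSE]
  attr(out, "rescaled") <- attr(base, "rescaled")
  out
}
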