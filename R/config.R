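#' Analysis configuration
#'
#' Collects the tuning parameters shared across the pipeline: the Zellner
#' g-prior scale, the activation half-width delta, the PC-algorithm
#' significance levels and subsampling settings used for prior calibration,
#' the model-search regime switch, and seeds for all stochastic steps.
#'
#' @param g Zellner g-prior scale. `NULL` (default) means the
#'   unit-information choice `g = n`, resolved when a regression problem is
#'   built.
#' @param delta Half-width of the neutral interval around zero on the
#'   centered protein scale; posterior-predictive mass below `-delta`,
#'   within `[-delta, delta]`, and above `delta` defines the suppressed /
#'   neutral / activated probabilities. Default 0.5.
#' @param alpha_init Significance level for the initial PC fit that defines
#'   the candidate edge set. Default 0.1; the value is deliberately liberal
#'   so the candidate set is large, and is configurable.
#' @param alpha_grid Strictly increasing grid of significance levels used in
#'   the stability subsampling. Default: 100 equally spaced points in
#'   (0, 0.1), endpoints excluded.
#' @param n_subsamples Number of half-sample draws for stability selection
#'   (default 100).
#' @param enumeration_limit Maximum candidate count for exact model
#'   enumeration; larger problems use the MC3 sampler. Default 20.
#' @param mcmc_iters MC3 iterations when sampling is used (default 50000).
#' @param default_upstream_prior Prior inclusion probability for upstream
#'   (mRNA / methylation-component / miRNA) covariates, which have no
#'   PPI or causal-structure information. Default 0.5 (noninformative).
#' @param seed Integer seed governing every stochastic step.
#' @param permutation_reps Number of permutation refits for the
#'   connectivity-score p-value (default 100).
#' @param gap_B Number of reference datasets for the gap statistic
#'   (default 50).
#'
#' @return An object of class `pronet_config` (a validated list).
#' @export
pronet_config <- function(g = NULL,
                          delta = 0.5,
                          alpha_init = 0.1,
                          alpha_grid = NULL,
                          n_subsamples = 100,
                          enumeration_limit = 20,
                          mcmc_iters = 50000,
                          default_upstream_prior = 0.5,
                          seed = 1L,
                          permutation_reps = 100,
                          gap_B = 50) {
  if (is.null(alpha_grid)) {
    alpha_grid <- seq_len(100) * 0.1 / 101
  }
  cfg <- list(
    g = g, delta = delta, alpha_init = alpha_init, alpha_grid = alpha_grid,
    n_subsamples = as.integer(n_subsamples),
    enumeration_limit = as.integer(enumeration_limit),
    mcmc_iters = as.integer(mcmc_iters),
    default_upstream_prior = default_upstream_prior,
    seed = as.integer(seed),
    permutation_reps = as.integer(permutation_reps),
    gap_B = as.integer(gap_B)
  )
  validate_config(cfg)
  class(cfg) <- "pronet_config"
  cfg
}

validate_config <- function(cfg) {
  stopifnot(
    is.null(cfg$g) || (is.numeric(cfg$g) && cfg$g > 0),
    is.numeric(cfg$delta), cfg$delta > 0,
    cfg$alpha_init > 0, cfg$alpha_init < 1,
    all(cfg$alpha_grid > 0), all(cfg$alpha_grid < 1),
    cfg$n_subsamples >= 1,
    cfg$enumeration_limit >= 0,
    cfg$mcmc_iters >= 1,
    cfg$default_upstream_prior > 0, cfg$default_upstream_prior < 1,
    cfg$permutation_reps >= 1,
    cfg$gap_B >= 1
  )
  if (any(diff(cfg$alpha_grid) <= 0)) {
    stop("alpha_grid must be strictly increasing")
  }
  invisible(cfg)
}

#' @export
print.pronet_config <- function(x, ...) {
  cat("pronet analysis configuration\n")
  cat(sprintf("  g: %s   delta: %g\n",
              if (is.null(x$g)) "n (unit information)" else format(x$g),
              x$delta))
  cat(sprintf("  PC: alpha_init %g, %d grid points in (%g, %g), %d subsamples\n",
              x$alpha_init, length(x$alpha_grid), min(x$alpha_grid),
              max(x$alpha_grid), x$n_subsamples))
  cat(sprintf("  model search: enumeration up to %d candidates, MC3 %d iters\n",
              x$enumeration_limit, x$mcmc_iters))
  cat(sprintf("  upstream prior %g, permutation reps %d, gap B %d, seed %d\n",
              x$default_upstream_prior, x$permutation_reps, x$gap_B, x$seed))
  invisible(x)
}

## Derive a substream seed from the master seed and a character tag,
## keeping the result in 32-bit integer range.
substream_seed <- function(seed, tag) {
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  as.integer((as.numeric(seed) * 7919 + h) %% .Machine$integer.max)
}
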