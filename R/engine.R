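#' Engine configuration for expected-spectrum computation
#'
#' The expected joint SFS is computed by Monte-Carlo structured-coalescent
#' branch-length accumulation: genealogies are simulated backward under the
#' model's event list and the branch length subtending exactly (i, j)
#' sampled copies accumulates into cell (i, j); the average over replicates
#' is the expected spectrum per unit theta. With `crn = TRUE` (common
#' random numbers) every likelihood evaluation within a fit reuses the same
#' seed, which makes the composite-likelihood surface deterministic and
#' smooth enough for direct search.
#'
#' @param n_reps genealogy replicates per evaluation (>= 100).
#' @param seed base seed of the genealogy stream.
#' @param crn reuse the same stream for every evaluation?
#' @export
engine_config <- function(n_reps = 5000, seed = 1, crn = TRUE) {
  stopifnot(n_reps >= 100)
  structure(list(n_reps = as.integer(n_reps), seed = as.integer(seed),
                 crn = isTRUE(crn)), class = "engine_config")
}

#' Expected joint SFS under a demographic model
#'
#' @param model a [dem_model()].
#' @param params named parameter values.
#' @param sizes gene-copy sample sizes `(n1, n2)` for (source, colony);
#'   small sizes (<= c(40, 20)) keep the Monte-Carlo budget reasonable.
#' @param engine an [engine_config()].
#' @return a [joint_sfs()] of per-unit-theta expected counts with an `se`
#'   attribute (per-cell Monte-Carlo standard errors).
#' @export
expected_sfs <- function(model, params, sizes = c(20, 10),
                         engine = engine_config()) {
  sc <- model_to_scenario(model, params)
  simulate_expected_sfs(sc, sample_sizes = sizes,
                        demes = c("pop1", "pop2"),
                        n_reps = engine$n_reps, seed = engine$seed)
}

#' Poisson composite log-likelihood of an observed spectrum
#'
#' Treats unmasked SFS cells as independent Poisson counts around
#' `theta_hat * model`, with the scaling `theta_hat = sum(obs) / sum(model)`
#' profiled analytically (its Poisson MLE):
#' `logL = sum(obs log(theta model) - theta model - log Gamma(obs + 1))`.
#' Model cells that are zero where the observation is positive are floored
#' at `eps` with a warning.
#'
#' @param model_sfs,obs_sfs [joint_sfs()] objects of identical shape and
#'   mask.
#' @param eps floor for zero model cells.
#' @return list with `loglik` and `theta_hat`.
#' @export
poisson_loglik <- function(model_sfs, obs_sfs, eps = 1e-12) {
  if (!all(dim(model_sfs$counts) == dim(obs_sfs$counts)))
    stop("model and observed spectra have different shapes")
  use <- !(model_sfs$mask | obs_sfs$mask)
  m <- model_sfs$counts[use]
  o <- obs_sfs$counts[use]
  if (any(m <= 0 & o > 0)) {
    warning("model cells of 0 where observations are positive; floored at ",
            format(eps))
    m[m <= 0 & o > 0] <- eps
  }
  theta <- sum(o) / sum(m)
  mu <- theta * m
  ll <- sum(ifelse(o > 0, o * log(mu), 0) - mu - lgamma(o + 1))
  list(loglik = ll, theta_hat = theta)
}

#' Akaike information criterion
#'
#' @param loglik maximized log-likelihood.
#' @param k number of estimated parameters.
#' @export
aic <- function(loglik, k) {
  stopifnot(k >= 0)
  -2 * loglik + 2 * k
}
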