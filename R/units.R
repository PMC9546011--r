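#' Physical unit scaling
#'
#' Converts coalescent-scaled estimates into individuals and years. The
#' reference size comes from the fitted spectrum scaling:
#' `N_ref = theta_hat / (4 mu L)`. Effective sequence length `L` should be
#' the total bases retained after quality filtering multiplied by the
#' fraction of called SNPs that made it into the fitted spectrum.
#'
#' @param mu per-base per-generation mutation rate.
#' @param gen_time generation time in years.
#' @param L effective sequence length in bases.
#' @export
unit_scaling <- function(mu = 8.4e-9, gen_time = 0.3, L = 1e6) {
  stopifnot(mu > 0, gen_time > 0, L > 0)
  structure(list(mu = mu, gen_time = gen_time, L = L),
            class = "unit_scaling")
}

#' Convert fitted parameters to physical units
#'
#' Sizes `nu` become `nu * N_ref` individuals; times `T` become
#' `T * 2 * N_ref` generations (and years via the generation time);
#' migration is reported both as the scaled rate and as the fraction of the
#' receiving deme replaced per generation, `m / (2 N_ref)`.
#'
#' @param fit an `expansion_fit` (its best run is used), or a named
#'   parameter vector together with `model` and `theta_hat`.
#' @param scaling a [unit_scaling()].
#' @param model,theta_hat required when `fit` is a plain parameter vector.
#' @return tibble `name`, `kind`, `coalescent`, `physical`, `unit` with an
#'   `n_ref` attribute.
#' @export
convert_units <- function(fit, scaling = unit_scaling(), model = NULL,
                          theta_hat = NULL) {
  if (inherits(fit, "expansion_fit")) {
    b <- fit$runs[fit$best, ]
    params <- unlist(b$params[[1]])
    model <- fit$model
    theta_hat <- b$theta_hat
  } else {
    params <- unlist(fit)
    if (is.null(model) || is.null(theta_hat))
      stop("supply model and theta_hat with a plain parameter vector")
  }
  if (theta_hat <= 0) stop("theta_hat must be positive")
  n_ref <- theta_hat / (4 * scaling$mu * scaling$L)
  tab <- model$params
  rows <- lapply(seq_len(nrow(tab)), function(j) {
    nm <- tab$name[j]
    v <- params[[nm]]
    switch(tab$kind[j],
      size = tibble(name = nm, kind = "size", coalescent = v,
                    physical = v * n_ref, unit = "individuals"),
      time = dplyr::bind_rows(
        tibble(name = nm, kind = "time", coalescent = v,
               physical = v * 2 * n_ref, unit = "generations"),
        tibble(name = nm, kind = "time", coalescent = v,
               physical = v * 2 * n_ref * scaling$gen_time,
               unit = "years")),
      migration = dplyr::bind_rows(
        tibble(name = nm, kind = "migration", coalescent = v, physical = v,
               unit = "2*N_ref*m (scaled)"),
        tibble(name = nm, kind = "migration", coalescent = v,
               physical = v / (2 * n_ref),
               unit = "fraction replaced per generation")),
      tibble(name = nm, kind = tab$kind[j], coalescent = v, physical = v,
             unit = "dimensionless"))
  })
  out <- dplyr::bind_rows(
    tibble(name = "N_ref", kind = "size", coalescent = 1,
           physical = n_ref, unit = "individuals"),
    dplyr::bind_rows(rows))
  attr(out, "n_ref") <- n_ref
  out
}
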