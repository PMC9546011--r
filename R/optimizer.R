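#' Optimizer configuration for sequential step-down fitting
#'
#' Pass 1 draws starting points log-uniform within the parameter bounds;
#' every later pass perturbs the AIC-weighted average of the previous
#' pass's completed runs by its fold factor (and seeds one run from the
#' best parameters found so far, so the best AIC never worsens across
#' passes). Each run performs a bounded Nelder-Mead search in transformed
#' (logit-of-log) parameter space under a wall-clock timeout; timed-out
#' runs are reported but excluded from weighting.
#'
#' @param passes number of sequential passes (>= 1).
#' @param runs_per_pass independent searches per pass.
#' @param fold multiplicative perturbation per pass (recycled/truncated to
#'   `passes`; the first entry is unused by pass 1).
#' @param maxit Nelder-Mead iteration cap per run.
#' @param timeout per-run wall-clock limit in seconds.
#' @param seed seed of the optimizer's own randomness (starts,
#'   perturbations).
#' @param search_reps genealogy replicates used *during* the Nelder-Mead
#'   search (coarse surface); every run's optimum is re-scored at the
#'   engine's full replicate count, which is what the reported likelihoods
#'   and AICs are computed from. `NULL` searches at full resolution.
#' @export
optimizer_config <- function(passes = 4, runs_per_pass = 30,
                             fold = c(3, 2, 2, 1), maxit = 200,
                             timeout = 60, seed = 1, search_reps = NULL) {
  stopifnot(passes >= 1, runs_per_pass >= 1, timeout > 0)
  fold <- rep_len(fold, passes)
  structure(list(passes = as.integer(passes),
                 runs_per_pass = as.integer(runs_per_pass),
                 fold = fold, maxit = as.integer(maxit),
                 timeout = timeout, seed = as.integer(seed),
                 search_reps = search_reps),
            class = "optimizer_config")
}

# bounded transform: search space y in R -> parameter in [lower, upper]
# (geometric for log-scaled parameters, linear otherwise)
par_from_y <- function(y, tab) {
  z <- 1 / (1 + exp(-y))
  ifelse(tab$log_scale,
         tab$lower * (tab$upper / tab$lower)^z,
         tab$lower + (tab$upper - tab$lower) * z)
}

y_from_par <- function(p, tab) {
  p <- pmin(pmax(p, tab$lower * (1 + 1e-10)), tab$upper * (1 - 1e-10))
  z <- ifelse(tab$log_scale,
              log(p / tab$lower) / log(tab$upper / tab$lower),
              (p - tab$lower) / (tab$upper - tab$lower))
  z <- pmin(pmax(z, 1e-8), 1 - 1e-8)
  log(z / (1 - z))
}

#' AIC-weighted restart point
#'
#' Akaike weights `w_i = exp(-Delta_i / 2) / sum exp(-Delta_j / 2)` with
#' `Delta_i = AIC_i - min AIC` over the completed (non-timeout) runs; the
#' restart is the weighted average of their parameter vectors, taken on log
#' scale for log-scaled parameters and clipped to the bounds. All but the
#' worst runs contribute some weight.
#'
#' @param runs tibble with columns `aic`, `timeout` and a `params`
#'   list-column of named vectors.
#' @param model the [dem_model()] supplying scales and bounds.
#' @return named parameter vector.
#' @export
akaike_weighted_start <- function(runs, model) {
  ok <- !runs$timeout & is.finite(runs$aic)
  if (!any(ok)) stop("no completed runs to weight")
  runs <- runs[ok, ]
  delta <- runs$aic - min(runs$aic)
  w <- exp(-delta / 2)
  w <- w / sum(w)
  tab <- model$params
  pmat <- do.call(rbind, lapply(runs$params, function(p) unlist(p)[tab$name]))
  out <- vapply(seq_len(nrow(tab)), function(j) {
    if (tab$log_scale[j]) exp(sum(w * log(pmat[, j])))
    else sum(w * pmat[, j])
  }, numeric(1))
  setNames(pmin(pmax(out, tab$lower), tab$upper), tab$name)
}

#' Fit a demographic model to an observed joint SFS
#'
#' Maximizes the Poisson composite likelihood of the observed spectrum over
#' the model's parameters with the AIC-weighted sequential step-down
#' optimizer, returning every run from every pass with full provenance.
#'
#' @param obs_sfs observed polarized two-population [joint_sfs()] (corners
#'   masked).
#' @param model a [dem_model()].
#' @param optimizer an [optimizer_config()].
#' @param engine an [engine_config()]; with `crn = TRUE` the likelihood at
#'   identical parameters is identical across evaluations.
#' @return object of class `expansion_fit`: list with `runs` (tibble),
#'   `model`, `best` (row index), configs.
#' @export
fit_model <- function(obs_sfs, model, optimizer = optimizer_config(),
                      engine = engine_config()) {
  if (length(obs_sfs$sizes) != 2)
    stop("fit_model requires a two-population spectrum")
  if (!obs_sfs$polarized) stop("fit_model requires a polarized spectrum")
  tab <- model$params
  sizes <- obs_sfs$sizes
  eval_seed <- engine$seed
  t_run_start <- NULL
  eval_count <- 0L
  objective <- function(y) {
    if (as.numeric(proc.time()["elapsed"]) - t_run_start > optimizer$timeout)
      stop(structure(class = c("fit_timeout", "error", "condition"),
                     list(message = "run timeout", call = NULL)))
    eval_count <<- eval_count + 1L
    p <- setNames(par_from_y(y, tab), tab$name)
    seed <- if (engine$crn) eval_seed else eval_seed + eval_count
    reps <- if (is.null(optimizer$search_reps)) engine$n_reps
            else optimizer$search_reps
    sfs <- tryCatch(
      expected_sfs(model, as.list(p), sizes = sizes,
                   engine = engine_config(reps, seed, engine$crn)),
      error = function(e) NULL)
    if (is.null(sfs)) return(1e12) # non-coalescing corner of parameter space
    # floor empty MC cells at a quarter of the engine's resolution: cells
    # below ~1/reps cannot be distinguished from zero by the engine
    -suppressWarnings(poisson_loglik(sfs, obs_sfs, eps = 0.25 / reps))$loglik
  }

  runs <- NULL
  weighted <- NULL
  best_par <- NULL
  best_nll <- Inf
  rng <- optimizer$seed
  for (pass in seq_len(optimizer$passes)) {
    starts <- withr::with_seed(rng + pass, {
      lapply(seq_len(optimizer$runs_per_pass), function(r) {
        if (pass == 1 || is.null(weighted)) {
          z <- runif(nrow(tab))
          p <- ifelse(tab$log_scale,
                      tab$lower * (tab$upper / tab$lower)^z,
                      tab$lower + (tab$upper - tab$lower) * z)
          setNames(p, tab$name)
        } else if (r == 1 && !is.null(best_par)) {
          best_par
        } else {
          fold <- optimizer$fold[pass]
          p <- weighted * fold^runif(nrow(tab), -1, 1)
          setNames(pmin(pmax(p, tab$lower), tab$upper), tab$name)
        }
      })
    })
    for (r in seq_len(optimizer$runs_per_pass)) {
      y0 <- y_from_par(unlist(starts[[r]]), tab)
      t_run_start <- as.numeric(proc.time()["elapsed"])
      t0 <- t_run_start
      res <- tryCatch(
        optim(y0, objective, method = "Nelder-Mead",
              control = list(maxit = optimizer$maxit)),
        fit_timeout = function(e) NULL)
      elapsed <- as.numeric(proc.time()["elapsed"]) - t0
      if (is.null(res)) {
        runs <- dplyr::bind_rows(runs, tibble(
          model = model$name, pass = pass, run = r,
          loglik = NA_real_, theta_hat = NA_real_, aic = NA_real_,
          runtime_s = elapsed, converged = FALSE, timeout = TRUE,
          params = list(starts[[r]])))
        next
      }
      p <- setNames(par_from_y(res$par, tab), tab$name)
      # recompute at the optimum to also recover theta_hat
      sfs <- expected_sfs(model, as.list(p), sizes = sizes,
                          engine = engine_config(engine$n_reps, eval_seed,
                                                 TRUE))
      pl <- suppressWarnings(poisson_loglik(sfs, obs_sfs,
                                            eps = 0.25 / engine$n_reps))
      this_aic <- aic(pl$loglik, model$k)
      runs <- dplyr::bind_rows(runs, tibble(
        model = model$name, pass = pass, run = r,
        loglik = pl$loglik, theta_hat = pl$theta_hat, aic = this_aic,
        runtime_s = elapsed, converged = res$convergence == 0,
        timeout = FALSE, params = list(p)))
      if (-pl$loglik < best_nll) {
        best_nll <- -pl$loglik
        best_par <- p
      }
    }
    done <- runs[runs$pass == pass & !runs$timeout, ]
    if (nrow(done) > 0) weighted <- akaike_weighted_start(done, model)
    if (is.null(weighted)) weighted <- best_par
    if (is.null(weighted) && pass == optimizer$passes)
      stop("no optimization run completed")
  }
  if (all(runs$timeout)) stop("no optimization run completed")
  structure(list(runs = runs, model = model,
                 best = which.min(runs$aic),
                 optimizer = optimizer, engine = engine,
                 sizes = sizes),
            class = "expansion_fit")
}

#' @export
print.expansion_fit <- function(x, ...) {
  b <- x$runs[x$best, ]
  cat("<expansion_fit> ", x$model$name, ": ", nrow(x$runs), " runs (",
      sum(x$runs$timeout), " timed out); best AIC ",
      format(round(b$aic, 2)), " in pass ", b$pass, "\n", sep = "")
  invisible(x)
}

#' Tidy fitted runs into one row per run
#'
#' @param x an `expansion_fit`.
#' @param ... unused.
#' @method tidy expansion_fit
#' @export
tidy.expansion_fit <- function(x, ...) {
  wide <- dplyr::bind_rows(lapply(x$runs$params, function(p) as_tibble(as.list(p))))
  dplyr::bind_cols(x$runs[, setdiff(names(x$runs), "params")], wide)
}

#' One-row summary of the best run
#'
#' @inheritParams tidy.expansion_fit
#' @method glance expansion_fit
#' @export
glance.expansion_fit <- function(x, ...) {
  b <- x$runs[x$best, ]
  tibble(model = x$model$name, loglik = b$loglik, aic = b$aic,
         theta_hat = b$theta_hat, n_runs = nrow(x$runs),
         n_timeout = sum(x$runs$timeout), best_pass = b$pass)
}

#' Write fitted runs as TSV and JSON
#'
#' One row per run with pass, seeds and AIC, ready for AIC-cloud scatter
#' plots.
#'
#' @param fit an `expansion_fit`.
#' @param path output TSV path (a `.json` sidecar is written as well).
#' @export
write_fit <- function(fit, path) {
  td <- tidy(fit)
  utils::write.table(td, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(model = fit$model$name,
                            optimizer_seed = fit$optimizer$seed,
                            engine_seed = fit$engine$seed,
                            runs = td),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}
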