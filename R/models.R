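#' Two-population founder-event demographic models
#'
#' The four candidate structures for a source population founding an island
#' colony, expressed in coalescent scaling (sizes nu relative to N_ref,
#' times in units of 2 N_ref generations, scaled migration 2 N_ref m,
#' founding fraction s):
#'
#' * `found_and_grow` — constant-size source; founding at `t_f` with
#'   fraction `s`; post-split growth in both demes to `nu_n` / `nu_h`;
#'   constant symmetric migration `m` from the founding onward.
#' * `three_epoch` — as above, but the source passes through two size
#'   changes before the founding (`nu_a1` then `nu_a2`, held for `dt1` and
#'   `dt2`), and migration starts only after a brief lag (a fixed 10% of
#'   `t_f`) following the founding.
#' * `two_epoch_admixture` — founding and growth as `found_and_grow`, but a
#'   single admixture pulse (at fraction `t_adm_frac` of `t_f`, strength
#'   `f`, source into colony) replaces continuous migration.
#' * `zhan` — a single source size change (`nu_a1`, `dt1` before founding)
#'   that persists to the present, post-split growth in the colony only,
#'   constant migration.
#'
#' Post-event size changes follow exponential curves by default or logistic
#' curves (capacity at the epoch's final size, rate implied by the epoch
#' duration).
#'
#' @param name model name.
#' @param growth growth-curve family for post-event size changes.
#' @return a `dem_model` with a parameter table (name, kind, bounds,
#'   log-scale flag).
#' @export
dem_model <- function(name = c("found_and_grow", "three_epoch",
                               "two_epoch_admixture", "zhan"),
                      growth = c("exponential", "logistic")) {
  name <- match.arg(name)
  growth <- match.arg(growth)
  p <- function(nm, kind, lo, hi, log = TRUE)
    tibble(name = nm, kind = kind, lower = lo, upper = hi, log_scale = log)
  size <- function(nm) p(nm, "size", 1e-3, 50)
  tim <- function(nm) p(nm, "time", 1e-3, 3)
  params <- switch(name,
    found_and_grow = dplyr::bind_rows(
      p("s", "fraction", 1e-4, 0.95), tim("t_f"),
      size("nu_n"), size("nu_h"), p("m", "migration", 1e-6, 5)),
    three_epoch = dplyr::bind_rows(
      size("nu_a1"), size("nu_a2"), tim("dt1"), tim("dt2"),
      p("s", "fraction", 1e-4, 0.95), tim("t_f"),
      size("nu_n"), size("nu_h"), p("m", "migration", 1e-6, 5)),
    two_epoch_admixture = dplyr::bind_rows(
      p("s", "fraction", 1e-4, 0.95), tim("t_f"),
      size("nu_n"), size("nu_h"),
      p("t_adm_frac", "fraction", 0.02, 0.98, log = FALSE),
      p("f", "fraction", 1e-6, 0.95)),
    zhan = dplyr::bind_rows(
      size("nu_a1"), tim("dt1"),
      p("s", "fraction", 1e-4, 0.95), tim("t_f"),
      size("nu_h"), p("m", "migration", 1e-6, 5)))
  structure(list(name = name, growth = growth, params = params,
                 k = nrow(params) + 1L), # + the profiled theta
            class = "dem_model")
}

#' @export
print.dem_model <- function(x, ...) {
  cat("<dem_model> ", x$name, " (", x$growth, " growth), ",
      nrow(x$params), " free parameters + theta\n", sep = "")
  invisible(x)
}

check_params <- function(model, params) {
  need <- model$params$name
  if (!all(need %in% names(params)))
    stop("missing parameter(s): ",
         paste(setdiff(need, names(params)), collapse = ", "))
  v <- unlist(params[need])
  lo <- model$params$lower
  hi <- model$params$upper
  if (any(v < lo - 1e-12) || any(v > hi + 1e-12))
    stop("parameter(s) out of bounds: ",
         paste(need[v < lo | v > hi], collapse = ", "))
  as.list(v)
}

# growth epoch helper: fall back to exponential when a logistic epoch would
# not be a forward growth (logistic needs nu1 < nu0)
growth_curve <- function(growth, nu0, nu1) {
  if (growth == "logistic" && nu1 < nu0) "logistic" else "exponential"
}

#' Instantiate a model as a two-deme scenario
#'
#' Translates a `dem_model` plus a named parameter list into the
#' [demographic_scenario()] the coalescent engine consumes. Deme `pop1` is
#' the source, `pop2` the founded colony.
#'
#' @param model a [dem_model()].
#' @param params named list/vector of parameter values.
#' @param n_ref reference size carried through to the scenario.
#' @export
model_to_scenario <- function(model, params, n_ref = 1e4) {
  pv <- check_params(model, as.list(params))
  g <- model$growth
  qdf <- function(...) {
    l <- list(...)
    n <- max(lengths(l))
    structure(lapply(l, rep_len, n), class = "data.frame",
              row.names = .set_row_names(n))
  }
  col_curve <- function(nu_start) growth_curve(g, pv$nu_h, nu_start)
  founding <- function(t_f, s) qdf(time = t_f, type = "founding",
                                   source = "pop1", target = "pop2",
                                   fraction = s)
  sym_mig <- function(rate, t1) qdf(to = c("pop1", "pop2"),
                                    from = c("pop2", "pop1"),
                                    rate = rate, t0 = 0, t1 = t1)
  sc <- with(pv, switch(model$name,
    found_and_grow = list(
      epochs = qdf(deme = c("pop1", "pop1", "pop2"),
                   t0 = c(0, t_f, 0), t1 = c(t_f, Inf, t_f),
                   nu0 = c(nu_n, 1, nu_h), nu1 = c(1, 1, s),
                   curve = c(growth_curve(g, nu_n, 1), "constant",
                             col_curve(s))),
      events = founding(t_f, s),
      migration = sym_mig(m, t_f)),
    three_epoch = list(
      epochs = qdf(deme = c(rep("pop1", 4), "pop2"),
                   t0 = c(0, t_f, t_f + dt2, t_f + dt2 + dt1, 0),
                   t1 = c(t_f, t_f + dt2, t_f + dt2 + dt1, Inf, t_f),
                   nu0 = c(nu_n, nu_a2, nu_a1, 1, nu_h),
                   nu1 = c(nu_a2, nu_a2, nu_a1, 1, s * nu_a2),
                   curve = c(growth_curve(g, nu_n, nu_a2), "constant",
                             "constant", "constant",
                             col_curve(s * nu_a2))),
      events = founding(t_f, s),
      migration = sym_mig(m, 0.9 * t_f)), # migration lag after founding
    two_epoch_admixture = list(
      epochs = qdf(deme = c("pop1", "pop1", "pop2"),
                   t0 = c(0, t_f, 0), t1 = c(t_f, Inf, t_f),
                   nu0 = c(nu_n, 1, nu_h), nu1 = c(1, 1, s),
                   curve = c(growth_curve(g, nu_n, 1), "constant",
                             col_curve(s))),
      events = qdf(time = c(t_f, t_adm_frac * t_f),
                   type = c("founding", "pulse"),
                   source = "pop1", target = "pop2",
                   fraction = c(s, f)),
      migration = NULL),
    zhan = list(
      epochs = qdf(deme = c("pop1", "pop1", "pop2"),
                   t0 = c(0, t_f + dt1, 0), t1 = c(t_f + dt1, Inf, t_f),
                   nu0 = c(nu_a1, 1, nu_h), nu1 = c(nu_a1, 1, s * nu_a1),
                   curve = c("constant", "constant",
                             col_curve(s * nu_a1))),
      events = founding(t_f, s),
      migration = sym_mig(m, t_f))))
  demographic_scenario(sc$epochs, events = sc$events,
                       migration = sc$migration, labels = c("pop1", "pop2"),
                       n_ref = n_ref)
}
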