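#' Multi-deme demographic scenarios
#'
#' A `demographic_scenario` describes, in coalescent scaling, a set of demes
#' with piecewise size trajectories, continuous migration windows, and
#' discrete founding / admixture events. Time runs backward from the present
#' (t = 0) in units of `2 * N_ref` generations; deme sizes are relative to
#' `N_ref`; migration rates are the scaled rates `2 * N_ref * m` where `m` is
#' the fraction of the receiving deme replaced per generation.
#'
#' @param epochs tibble with columns `deme` (label), `t0`, `t1` (epoch
#'   bounds, backward time, `t1` may be `Inf`), `nu0` (size at the recent end
#'   `t0`), `nu1` (size at the old end `t1`) and `curve` (one of
#'   `"constant"`, `"exponential"`, `"logistic"`). Epochs must tile
#'   `[0, founding time)` for founded demes and `[0, Inf)` for the root deme.
#' @param events tibble with columns `time`, `type` (`"founding"` or
#'   `"pulse"`), `source`, `target` (deme labels) and `fraction`. A founding
#'   event removes `target` backward in time (all its lineages join
#'   `source`); its `fraction` records the founding bottleneck s and is used
#'   by scenario builders to set the founded deme's initial size. A pulse
#'   moves each `target` lineage to `source` with probability `fraction`.
#' @param migration tibble with columns `to`, `from`, `rate`, `t0`, `t1`:
#'   forward migration into `to` from `from` at scaled rate `rate` over the
#'   backward-time window `[t0, t1)`.
#' @param labels deme labels in order; defaults to the demes named in
#'   `epochs`.
#' @param n_ref reference effective size (diploid individuals), used for
#'   capacity checks and unit conversion of simulated data.
#' @param coords optional tibble `deme`, `lat`, `lon` (decimal degrees).
#'
#' @return an object of class `demographic_scenario`.
#' @export
demographic_scenario <- function(epochs, events = NULL, migration = NULL,
                                 labels = NULL, n_ref = 1e4, coords = NULL) {
  epochs <- as_tibble(epochs)
  stopifnot(all(c("deme", "t0", "t1", "nu0", "nu1", "curve") %in% names(epochs)))
  if (is.null(labels)) labels <- unique(epochs$deme)
  if (is.null(events)) {
    events <- tibble(time = numeric(), type = character(),
                     source = character(), target = character(),
                     fraction = numeric())
  } else {
    events <- as_tibble(events)
  }
  if (is.null(migration)) {
    migration <- tibble(to = character(), from = character(),
                        rate = numeric(), t0 = numeric(), t1 = numeric())
  } else {
    migration <- as_tibble(migration)
  }
  sc <- structure(
    list(labels = labels, epochs = epochs, events = events,
         migration = migration, n_ref = n_ref, coords = coords),
    class = "demographic_scenario")
  validate_scenario(sc)
  sc
}

validate_scenario <- function(sc) {
  ep <- sc$epochs
  if (any(ep$nu0 <= 0) || any(ep$nu1 <= 0)) stop("all deme sizes must be > 0")
  if (any(ep$t1 <= ep$t0)) stop("epoch times must be strictly ordered (t1 > t0)")
  if (!all(ep$curve %in% c("constant", "exponential", "logistic")))
    stop("unknown size curve")
  if (!all(ep$deme %in% sc$labels)) stop("epoch for unknown deme")
  ev <- sc$events
  if (nrow(ev)) {
    if (!all(ev$type %in% c("founding", "pulse"))) stop("unknown event type")
    if (any(ev$fraction <= 0 | ev$fraction >= 1))
      stop("event fractions must lie in (0, 1)")
    if (any(ev$time <= 0)) stop("event times must be positive")
    if (!all(c(ev$source, ev$target) %in% sc$labels))
      stop("event references unknown deme")
  }
  founded <- ev$target[ev$type == "founding"]
  if (anyDuplicated(founded)) stop("a deme can only be founded once")
  root <- setdiff(sc$labels, founded)
  if (length(root) != 1)
    stop("every deme except a single root must trace to a founding event")
  # root must have an epoch reaching Inf
  if (!any(ep$deme == root & is.infinite(ep$t1)))
    stop("root deme must have a terminal epoch with t1 = Inf")
  if (!is.null(sc$coords)) {
    cc <- sc$coords
    if (any(cc$lat < -90 | cc$lat > 90) || any(cc$lon < -180 | cc$lon > 180))
      stop("coordinates out of range")
  }
  invisible(sc)
}

#' @export
print.demographic_scenario <- function(x, ...) {
  cat("<demographic_scenario> ", length(x$labels), " deme(s): ",
      paste(x$labels, collapse = ", "), "\n", sep = "")
  cat("  N_ref = ", format(x$n_ref), "; ", nrow(x$events), " event(s); ",
      nrow(x$migration), " migration window(s)\n", sep = "")
  invisible(x)
}

# size of a deme at backward time t (relative to N_ref)
scenario_size_at <- function(sc, deme, t) {
  ep <- sc$epochs[sc$epochs$deme == deme, ]
  row <- ep[ep$t0 <= t & t < ep$t1, ]
  if (nrow(row) == 0) {
    row <- ep[ep$t0 <= t & t <= ep$t1, ] # allow hitting the old end exactly
    if (nrow(row) == 0) stop("no epoch covers time ", t, " for deme ", deme)
    row <- row[1, ]
  }
  eval_size_curve(row$curve, row$nu0, row$nu1, row$t0, row$t1, t)
}

eval_size_curve <- function(curve, nu0, nu1, t0, t1, t) {
  switch(curve,
    constant = nu0,
    exponential = {
      g <- log(nu0 / nu1) / (t1 - t0)
      nu0 * exp(-g * (t - t0))
    },
    logistic = {
      pl <- logistic_params(nu0, nu1, t1 - t0)
      pl$K / (1 + pl$B * exp(pl$r * (t - t0)))
    })
}

# Backward-time logistic: carrying capacity K set so the recent end sits at
# 99% of K, rate implied by the epoch duration (size must traverse nu0 ->
# nu1 over dt). Requires nu1 < nu0 (forward growth toward the capacity).
logistic_params <- function(nu0, nu1, dt) {
  if (nu1 >= nu0) stop("logistic epochs require forward growth (nu1 < nu0)")
  K <- nu0 / 0.99
  B <- K / nu0 - 1
  r <- log((K / nu1 - 1) / B) / dt
  list(K = K, B = B, r = r)
}

# Flatten a demographic_scenario into the phase structure the C++ engine
# consumes: global phase boundaries, per-phase migration matrices and size
# rows (type, a, b, c), and backward event rows.
normalize_scenario <- function(sc) {
  labels <- sc$labels
  nd <- length(labels)
  idx <- setNames(seq_len(nd) - 1L, labels) # 0-based for C++
  ev <- sc$events
  n_ev <- nrow(ev)
  founded_at <- rep(Inf, nd)
  if (n_ev) {
    fo <- ev$type == "founding"
    founded_at[match(ev$target[fo], labels)] <- ev$time[fo]
  }
  ep_deme <- match(sc$epochs$deme, labels)
  ep_t0 <- sc$epochs$t0; ep_t1 <- sc$epochs$t1
  ep_nu0 <- sc$epochs$nu0; ep_nu1 <- sc$epochs$nu1
  ep_curve <- sc$epochs$curve
  mg <- sc$migration
  n_mg <- nrow(mg)
  if (n_mg) {
    mg_to <- match(mg$to, labels); mg_from <- match(mg$from, labels)
    mg_rate <- mg$rate; mg_t0 <- mg$t0; mg_t1 <- mg$t1
  }
  brk <- sort(unique(c(0, ep_t0, ep_t1[is.finite(ep_t1)],
                       if (n_mg) c(mg_t0, mg_t1[is.finite(mg_t1)]),
                       if (n_ev) ev$time)))
  brk <- brk[is.finite(brk)]
  P <- length(brk)
  mig_list <- vector("list", P)
  size_list <- vector("list", P)
  for (p in seq_len(P)) {
    b0 <- brk[p]
    b1 <- if (p < P) brk[p + 1] else Inf
    mid <- if (is.finite(b1)) (b0 + b1) / 2 else b0 + 1
    S <- matrix(0, nd, 4)
    for (d in seq_len(nd)) {
      if (founded_at[d] <= b0 + 1e-12) {
        S[d, ] <- c(0, 1, 0, 0) # dead deme: inert placeholder
        next
      }
      row <- which(ep_deme == d & ep_t0 <= b0 + 1e-12 & ep_t1 >= b1 - 1e-12)
      if (length(row) == 0)
        stop("no epoch of deme ", labels[d], " covers phase [", b0, ", ",
             b1, ")")
      row <- row[1]
      S[d, ] <- size_row(ep_curve[row], ep_nu0[row], ep_nu1[row],
                         ep_t0[row], ep_t1[row], b0)
    }
    M <- matrix(0, nd, nd)
    if (n_mg) {
      for (i in which(mg_t0 <= mid & mid < mg_t1)) {
        if (founded_at[mg_to[i]] <= b0 + 1e-12) next
        if (founded_at[mg_from[i]] <= b0 + 1e-12) next
        M[mg_to[i], mg_from[i]] <- M[mg_to[i], mg_from[i]] + mg_rate[i]
      }
    }
    mig_list[[p]] <- M
    size_list[[p]] <- S
  }
  if (n_ev) {
    ord <- order(ev$time)
    emat <- cbind(ev$time[ord],
                  ifelse(ev$type[ord] == "founding", 0, 1),
                  idx[ev$target[ord]], idx[ev$source[ord]],
                  ifelse(ev$type[ord] == "founding", 1, ev$fraction[ord]))
  } else {
    emat <- matrix(numeric(), 0, 5)
  }
  list(phases = list(breaks = brk, mig = mig_list, sizes = size_list),
       events = emat, n_demes = nd, idx = idx)
}

# size-spec row (type, a, b, c) anchored at phase start b0
size_row <- function(curve, nu0, nu1, t0, t1, b0) {
  switch(curve,
    constant = c(0, nu0, 0, 0),
    exponential = {
      g <- log(nu0 / nu1) / (t1 - t0)
      c(1, nu0 * exp(-g * (b0 - t0)), g, 0)
    },
    logistic = {
      pl <- logistic_params(nu0, nu1, t1 - t0)
      c(2, pl$K, pl$B * exp(pl$r * (b0 - t0)), pl$r)
    })
}

#' Serial founder-effect scenario preset
#'
#' Builds a chain of demes, each founded from its predecessor through a
#' strong bottleneck followed by growth back to its present-day size — the
#' stepwise colonization structure of island range expansions. Deme 1 is the
#' large constant-size source; deme k (k >= 2) is founded at backward time
#' `(n_demes - k + 1) * interval` with founding fraction `founder_fraction`
#' of its parent's size at that moment, then grows to `deme_size` by the
#' present. Demes are laid out on a line of coordinates for
#' isolation-by-distance work.
#'
#' @param n_demes number of demes in the chain (>= 2).
#' @param founder_fraction founding bottleneck s in (0, 1).
#' @param interval backward time between successive foundings
#'   (units of 2 N_ref generations).
#' @param growth post-founding growth curve.
#' @param migration scaled migration rate (`2 N_ref m`) between adjacent
#'   demes while both exist; 0 disables gene flow.
#' @param deme_size present-day size of founded demes relative to `N_ref`.
#' @param ancestral_size size of the source deme.
#' @param n_ref reference effective size.
#' @return a [demographic_scenario()].
#' @export
serial_founder_preset <- function(n_demes, founder_fraction = 0.02,
                                  interval = 0.1,
                                  growth = c("exponential", "logistic"),
                                  migration = 0.05, deme_size = 1,
                                  ancestral_size = 1, n_ref = 1e4) {
  growth <- match.arg(growth)
  if (n_demes < 2) stop("n_demes must be >= 2")
  if (founder_fraction <= 0 || founder_fraction >= 1)
    stop("founder_fraction must lie in (0, 1)")
  labels <- sprintf("deme%d", seq_len(n_demes))
  t_found <- c(Inf, (n_demes - seq(2, n_demes) + 1) * interval)
  epochs <- list(tibble(deme = labels[1], t0 = 0, t1 = Inf,
                        nu0 = ancestral_size, nu1 = ancestral_size,
                        curve = "constant"))
  # parent size at each founding time, walking down the chain
  size_at <- function(k, t) {
    if (k == 1) return(ancestral_size)
    tf <- t_found[k]
    nu_start <- founder_fraction * size_at(k - 1, tf)
    eval_size_curve(growth, deme_size, nu_start, 0, tf, t)
  }
  events <- NULL
  for (k in seq(2, n_demes)) {
    tf <- t_found[k]
    nu_start <- founder_fraction * size_at(k - 1, tf)
    epochs[[k]] <- tibble(deme = labels[k], t0 = 0, t1 = tf,
                          nu0 = deme_size, nu1 = nu_start, curve = growth)
    events <- dplyr::bind_rows(events, tibble(
      time = tf, type = "founding", source = labels[k - 1],
      target = labels[k], fraction = founder_fraction))
  }
  mig <- NULL
  if (migration > 0) {
    for (k in seq(2, n_demes)) {
      mig <- dplyr::bind_rows(mig,
        tibble(to = labels[k], from = labels[k - 1], rate = migration,
               t0 = 0, t1 = t_found[k]),
        tibble(to = labels[k - 1], from = labels[k], rate = migration,
               t0 = 0, t1 = t_found[k]))
    }
  }
  coords <- tibble(deme = labels, lat = 0,
                   lon = (seq_len(n_demes) - 1) * 12)
  demographic_scenario(dplyr::bind_rows(epochs), events = events,
                       migration = mig, labels = labels, n_ref = n_ref,
                       coords = coords)
}

#' Stepping-stone scenario preset
#'
#' Constant-size demes on a line exchanging migrants with their neighbours,
#' merging into a single ancestral deme at `t_merge`. Useful as the
#' equilibrium local-migration contrast to [serial_founder_preset()] when
#' testing isolation by distance.
#'
#' @inheritParams serial_founder_preset
#' @param t_merge backward time at which all demes collapse into deme 1.
#' @export
stepping_stone_preset <- function(n_demes, migration = 1, deme_size = 1,
                                  t_merge = 4, n_ref = 1e4) {
  if (n_demes < 2) stop("n_demes must be >= 2")
  labels <- sprintf("deme%d", seq_len(n_demes))
  epochs <- dplyr::bind_rows(
    tibble(deme = labels[1], t0 = 0, t1 = Inf, nu0 = deme_size,
           nu1 = deme_size, curve = "constant"),
    dplyr::bind_rows(lapply(seq(2, n_demes), function(k)
      tibble(deme = labels[k], t0 = 0, t1 = t_merge, nu0 = deme_size,
             nu1 = deme_size, curve = "constant"))))
  events <- dplyr::bind_rows(lapply(seq(2, n_demes), function(k)
    tibble(time = t_merge, type = "founding", source = labels[1],
           target = labels[k], fraction = 0.5)))
  mig <- dplyr::bind_rows(lapply(seq(2, n_demes), function(k)
    dplyr::bind_rows(
      tibble(to = labels[k], from = labels[k - 1], rate = migration,
             t0 = 0, t1 = t_merge),
      tibble(to = labels[k - 1], from = labels[k], rate = migration,
             t0 = 0, t1 = t_merge))))
  coords <- tibble(deme = labels, lat = 0,
                   lon = (seq_len(n_demes) - 1) * 12)
  demographic_scenario(epochs, events = events, migration = mig,
                       labels = labels, n_ref = n_ref, coords = coords)
}
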