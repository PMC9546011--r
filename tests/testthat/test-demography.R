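test_that("poisson_loglik matches hand-computed values and profiles theta", {
  # single unmasked cell obs = 2, model = 1
  m1 <- joint_sfs(c(0, 1, 0), 2)
  o1 <- joint_sfs(c(0, 2, 0), 2)
  pl <- poisson_loglik(m1, o1)
  expect_equal(pl$theta_hat, 2)
  expect_equal(pl$loglik, 2 * log(2) - 2 - log(2), tolerance = 1e-12)
  # theta is a ratio of sums: obs (2, 4), model (1, 1) -> 3
  m2 <- joint_sfs(c(0, 1, 1, 0), 3)
  o2 <- joint_sfs(c(0, 2, 4, 0), 3)
  expect_equal(poisson_loglik(m2, o2)$theta_hat, 3)
  # obs = c * model recovers theta = c at the saturated maximum
  set.seed(22)
  mod <- joint_sfs(runif(11, 0.5, 2), 10)
  obs <- joint_sfs(mod$counts * 7, 10)
  pl3 <- poisson_loglik(mod, obs)
  expect_equal(pl3$theta_hat, 7, tolerance = 1e-12)
  mu <- 7 * mod$counts[!mod$mask]
  sat <- sum(mu * log(mu) - mu - lgamma(mu + 1))
  expect_equal(pl3$loglik, sat, tolerance = 1e-9)
  # zero model cells with positive observations are floored with a warning
  mz <- joint_sfs(c(0, 0, 1, 0), 3)
  oz <- joint_sfs(c(0, 3, 1, 0), 3)
  expect_warning(poisson_loglik(mz, oz), "floored")
  expect_error(poisson_loglik(m1, joint_sfs(c(0, 1, 1, 0), 3)), "shapes")
})

test_that("aic is -2 logL + 2k and monotone in logL", {
  expect_equal(aic(-100, 5), 210)
  expect_equal(aic(0, 0), 0)
  expect_lt(aic(-10, 3), aic(-20, 3))
})

test_that("akaike_weighted_start reproduces the worked weight example", {
  model <- dem_model("found_and_grow")
  # linear-scale check first: use a fake linear parameter table
  runs <- tibble::tibble(
    aic = c(210, 212), timeout = FALSE,
    params = list(c(s = 0.1, t_f = 1, nu_n = 1, nu_h = 1, m = 1),
                  c(s = 0.1, t_f = 2, nu_n = 1, nu_h = 1, m = 1)))
  w <- exp(0) / (exp(0) + exp(-1))
  expect_equal(round(c(w, 1 - w), 4), c(0.7311, 0.2689))
  start <- akaike_weighted_start(runs, model)
  # t_f is log-scaled in the model: geometric weighting
  expect_equal(start[["t_f"]], exp(w * log(1) + (1 - w) * log(2)),
               tolerance = 1e-12)
  # single run passes through unchanged
  expect_equal(akaike_weighted_start(runs[1, ], model)[["t_f"]], 1)
  # equal AICs -> geometric mean for log-scaled parameters
  runs_eq <- runs; runs_eq$aic <- c(210, 210)
  expect_equal(akaike_weighted_start(runs_eq, model)[["t_f"]], sqrt(2),
               tolerance = 1e-12)
  # timed-out runs are excluded from the weighting
  runs_to <- dplyr::bind_rows(runs, tibble::tibble(
    aic = NA_real_, timeout = TRUE,
    params = list(c(s = 0.9, t_f = 5, nu_n = 99, nu_h = 99, m = 19))))
  expect_equal(akaike_weighted_start(runs_to, model),
               akaike_weighted_start(runs, model))
  expect_error(akaike_weighted_start(runs_to[3, ], model), "no completed")
})

test_that("expected_sfs degenerates to a single deme when the split vanishes", {
  m <- dem_model("found_and_grow")
  # s -> 1 is outside (0,1) bounds; use s near 1, no size change, no
  # migration, founding almost now: the two demes behave as one
  pars <- list(s = 0.93, t_f = 0.001, nu_n = 1, nu_h = 1, m = 1e-6)
  s <- expected_sfs(m, pars, sizes = c(6, 6),
                    engine = engine_config(8000, seed = 6))
  tot <- marginalize(s, 1)$counts[, 1] # not meaningful alone; use sum below
  # pooled spectrum over total derived count should be the n=12 neutral SFS
  pooled <- numeric(13)
  for (i in 0:6) for (j in 0:6)
    pooled[i + j + 1] <- pooled[i + j + 1] + s$counts[i + 1, j + 1]
  i <- 1:11
  expect_equal(pooled[i + 1], 1 / i, tolerance = 0.12)
})

test_that("expected-SFS mass is per unit theta and scales out", {
  m <- dem_model("zhan")
  pars <- list(nu_a1 = 2, dt1 = 0.2, s = 0.05, t_f = 0.2, nu_h = 1, m = 0.5)
  s1 <- expected_sfs(m, pars, sizes = c(8, 6),
                     engine = engine_config(2000, seed = 8))
  obs <- joint_sfs(s1$counts * 123, c(8, 6))
  expect_equal(poisson_loglik(s1, obs)$theta_hat, 123, tolerance = 1e-9)
})

test_that("likelihood prefers the generating parameters over perturbations", {
  m <- dem_model("found_and_grow")
  true <- list(s = 0.05, t_f = 0.3, nu_n = 4, nu_h = 2, m = 2)
  big <- expected_sfs(m, true, sizes = c(16, 8),
                      engine = engine_config(20000, seed = 9))
  set.seed(23)
  obs <- joint_sfs(matrix(rpois(length(big$counts), 2000 * big$counts),
                          nrow(big$counts)), c(16, 8))
  ll <- function(p) suppressWarnings(poisson_loglik(
    expected_sfs(m, p, sizes = c(16, 8), engine = engine_config(5000, seed = 10)),
    obs, eps = 0.25 / 5000))$loglik
  base <- ll(true)
  worse <- 0
  hi <- setNames(m$params$upper, m$params$name)
  lo <- setNames(m$params$lower, m$params$name)
  nm <- names(true)
  for (j in seq_along(true)) {
    up <- true; up[[j]] <- min(true[[j]] * 3, 0.99 * hi[[nm[j]]])
    dn <- true; dn[[j]] <- max(true[[j]] / 3, 1.01 * lo[[nm[j]]])
    worse <- worse + (ll(up) < base) + (ll(dn) < base)
  }
  expect_gte(worse, 9) # at least 9 of the 10 3x-perturbations fit worse
})

test_that("fit runs record provenance and CRN evaluations are deterministic", {
  m <- dem_model("found_and_grow")
  true <- list(s = 0.05, t_f = 0.3, nu_n = 2, nu_h = 1, m = 0.5)
  base <- expected_sfs(m, true, sizes = c(10, 6),
                       engine = engine_config(4000, seed = 12))
  set.seed(24)
  obs <- joint_sfs(matrix(rpois(length(base$counts), 500 * base$counts),
                          nrow(base$counts)), c(10, 6))
  opt <- optimizer_config(passes = 2, runs_per_pass = 3, fold = c(3, 2),
                          maxit = 15, timeout = 60, seed = 3,
                          search_reps = 500)
  fit <- fit_model(obs, m, optimizer = opt,
                   engine = engine_config(2000, seed = 13))
  expect_s3_class(fit, "expansion_fit")
  expect_equal(nrow(fit$runs), 6)
  expect_true(all(c("pass", "run", "loglik", "aic", "runtime_s",
                    "timeout") %in% names(fit$runs)))
  # CRN: re-evaluating the best parameters reproduces the recorded logL
  b <- fit$runs[fit$best, ]
  sfs <- expected_sfs(m, as.list(unlist(b$params[[1]])), sizes = c(10, 6),
                      engine = engine_config(2000, seed = 13))
  pl <- suppressWarnings(poisson_loglik(sfs, obs, eps = 0.25 / 2000))
  expect_equal(pl$loglik, b$loglik, tolerance = 1e-12)
  # tidy/glance interfaces
  td <- tidy(fit)
  expect_true(all(m$params$name %in% names(td)))
  expect_equal(nrow(glance(fit)), 1)
  # fit results serialize to TSV + JSON
  path <- withr::local_tempfile(fileext = ".tsv")
  write_fit(fit, path)
  expect_true(file.exists(path) && file.exists(paste0(path, ".json")))
})

test_that("best AIC is non-increasing across passes under shared seeds", {
  m <- dem_model("found_and_grow")
  true <- list(s = 0.05, t_f = 0.3, nu_n = 2, nu_h = 1, m = 0.5)
  base <- expected_sfs(m, true, sizes = c(10, 6),
                       engine = engine_config(4000, seed = 14))
  set.seed(25)
  obs <- joint_sfs(matrix(rpois(length(base$counts), 500 * base$counts),
                          nrow(base$counts)), c(10, 6))
  # full-resolution CRN search: the scored surface is the searched surface
  fit <- fit_model(obs, m,
                   optimizer = optimizer_config(passes = 3, runs_per_pass = 4,
                                                fold = c(3, 2, 1),
                                                maxit = 25, timeout = 120,
                                                seed = 7),
                   engine = engine_config(1500, seed = 15))
  best_by_pass <- tapply(fit$runs$aic, fit$runs$pass, min, na.rm = TRUE)
  expect_true(all(diff(best_by_pass) <= 1e-9))
})

test_that("per-run timeouts are flagged and excluded", {
  m <- dem_model("found_and_grow")
  true <- list(s = 0.05, t_f = 0.3, nu_n = 2, nu_h = 1, m = 0.5)
  base <- expected_sfs(m, true, sizes = c(10, 6),
                       engine = engine_config(2000, seed = 16))
  obs <- joint_sfs(round(base$counts * 500), c(10, 6))
  expect_error(
    fit_model(obs, m,
              optimizer = optimizer_config(passes = 1, runs_per_pass = 2,
                                           maxit = 500, timeout = 1e-4),
              engine = engine_config(2000, seed = 17)),
    "no optimization run completed")
})

test_that("unit conversion follows the coalescent scaling laws", {
  # N_ref = theta / (4 mu L)
  model <- dem_model("found_and_grow")
  params <- c(s = 0.05, t_f = 0.05, nu_n = 2, nu_h = 1, m = 0.4)
  sc1 <- unit_scaling(mu = 8.4e-9, gen_time = 0.3, L = 1e6)
  out <- convert_units(params, sc1, model = model, theta_hat = 336)
  expect_equal(attr(out, "n_ref"), 1e4)
  # T = 0.05 with N_ref = 1e5 -> 10,000 generations -> 3,000 years
  sc2 <- unit_scaling(mu = 8.4e-9, gen_time = 0.3, L = 1e5)
  out2 <- convert_units(params, sc2, model = model, theta_hat = 336)
  expect_equal(attr(out2, "n_ref"), 1e5)
  tf <- out2[out2$name == "t_f", ]
  expect_equal(tf$physical[tf$unit == "generations"], 10000)
  expect_equal(tf$physical[tf$unit == "years"], 3000)
  # switching to 7 generations / year and the slower mutation rate rescales
  # by the exact analytic factors
  sc3 <- unit_scaling(mu = 2.9e-9, gen_time = 1 / 7, L = 1e5)
  out3 <- convert_units(params, sc3, model = model, theta_hat = 336)
  expect_equal(attr(out3, "n_ref"), 1e5 * 8.4 / 2.9, tolerance = 1e-12)
  t3 <- out3[out3$name == "t_f", ]
  expect_equal(t3$physical[t3$unit == "years"],
               3000 * (8.4 / 2.9) * (1 / 7) / 0.3, tolerance = 1e-12)
  # sizes in individuals, migration as a per-generation fraction
  nun <- out2[out2$name == "nu_n", ]
  expect_equal(nun$physical, 2e5)
  mig <- out2[out2$name == "m", ]
  expect_equal(mig$physical[mig$unit == "fraction replaced per generation"],
               0.4 / (2 * 1e5))
  expect_error(convert_units(params, sc1, model = model, theta_hat = -1),
               "positive")
  expect_error(unit_scaling(mu = -1), "mu")
})

test_that("logistic growth variants run and stay positive", {
  m <- dem_model("found_and_grow", growth = "logistic")
  pars <- list(s = 0.02, t_f = 0.3, nu_n = 3, nu_h = 2, m = 0.5)
  s <- expected_sfs(m, pars, sizes = c(8, 6),
                    engine = engine_config(1500, seed = 18))
  expect_true(all(s$counts >= 0))
  expect_gt(sum(s$counts[!s$mask]), 0)
  # logistic epochs reach 99% of capacity at the recent end
  pl <- pacifex:::logistic_params(2, 0.04, 0.3)
  expect_equal(pl$K / (1 + pl$B), 2, tolerance = 1e-12)
  expect_equal(pl$K / (1 + pl$B * exp(pl$r * 0.3)), 0.04, tolerance = 1e-9)
})
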