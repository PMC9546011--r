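const_deme <- function(nu = 1, n_ref = 1e4) {
  demographic_scenario(
    tibble::tibble(deme = "A", t0 = 0, t1 = Inf, nu0 = nu, nu1 = nu,
                   curve = "constant"),
    labels = "A", n_ref = n_ref)
}

test_that("constant-deme expected SFS matches the 1/i neutral shape", {
  s <- simulate_expected_sfs(const_deme(), 10, n_reps = 8000, seed = 2)
  se <- attr(s, "se")
  i <- 1:9
  z <- (s$counts[i + 1, 1] - 1 / i) / se[i + 1, 1]
  expect_lt(max(abs(z)), 3.5)
})

test_that("ancient-split demes share no polymorphism", {
  sc <- demographic_scenario(
    dplyr::bind_rows(
      tibble::tibble(deme = "A", t0 = 0, t1 = Inf, nu0 = 1, nu1 = 1,
                     curve = "constant"),
      tibble::tibble(deme = "B", t0 = 0, t1 = 30, nu0 = 1, nu1 = 1,
                     curve = "constant")),
    events = tibble::tibble(time = 30, type = "founding", source = "A",
                            target = "B", fraction = 0.5),
    labels = c("A", "B"))
  s <- simulate_expected_sfs(sc, c(6, 6), n_reps = 2000, seed = 3)
  interior <- s$counts[2:6, 2:6]
  # shared interior polymorphism requires branches spanning the old split:
  # essentially all mass must sit in the private margins
  expect_lt(sum(interior), 0.01 * sum(s$counts[!s$mask]))
})

test_that("a symmetric island model gives an exchangeable spectrum", {
  sc <- stepping_stone_preset(2, migration = 2, t_merge = 5)
  s <- simulate_expected_sfs(sc, c(8, 8), n_reps = 6000, seed = 4)
  se <- attr(s, "se")
  asym <- abs(s$counts - t(s$counts)) /
    sqrt(pmax(se^2 + t(se)^2, 1e-12))
  expect_lt(stats::quantile(asym[!s$mask], 0.99), 4)
})

test_that("theta = 0 gives an empty SNP matrix; same seed is byte-identical", {
  sc <- const_deme()
  ds0 <- simulate_dataset(sc, 4, n_loci = 10, theta = 0, seed = 5)
  expect_equal(ncol(ds0$gm$calls), 0L)
  ds1 <- simulate_dataset(sc, 4, n_loci = 50, theta = 1, seed = 6)
  ds2 <- simulate_dataset(sc, 4, n_loci = 50, theta = 1, seed = 6)
  f1 <- withr::local_tempfile(fileext = ".vcf")
  f2 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(ds1$gm, f1)
  write_vcf(ds2$gm, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_false(identical(
    ds1$gm$calls,
    simulate_dataset(sc, 4, n_loci = 50, theta = 1, seed = 7)$gm$calls))
})

test_that("Watterson's estimator and pairwise diversity match theory", {
  # E[S] per locus = theta * a1(n); E[pi] per locus = theta
  theta <- 0.8
  n_dip <- 5
  sc <- const_deme()
  ds <- simulate_dataset(sc, n_dip, n_loci = 2000, theta = theta,
                         one_snp_per_locus = FALSE, seed = 8)
  a1 <- sum(1 / seq_len(2 * n_dip - 1))
  S_per_locus <- ncol(ds$gm$calls) / 2000
  se_S <- stats::sd(table(factor(ds$gm$loci$pos %/% 5e4,
                                 levels = 1:2000))) / sqrt(2000)
  expect_lt(abs(S_per_locus - theta * a1), 3 * se_S)
  # per-locus pairwise diversity: mean over loci of 2 p q * 2n/(2n-1),
  # summed per locus, estimates theta
  g <- ds$gm$calls
  p <- colMeans(g) / 2
  n <- 2 * n_dip
  pi_site <- 2 * p * (1 - p) * n / (n - 1)
  pi_locus <- sum(pi_site) / 2000
  se_pi <- 3 * theta / sqrt(2000) # loose: pi per locus has variance ~ theta^2
  expect_lt(abs(pi_locus - theta), 3 * se_pi)
})

test_that("missingness rate is honoured and capacity is checked", {
  sc <- const_deme(n_ref = 1e4)
  ds <- simulate_dataset(sc, 6, n_loci = 400, theta = 1,
                         missing_rate = 0.2, seed = 9)
  expect_equal(mean(is.na(ds$gm$calls)), 0.2, tolerance = 0.03)
  expect_error(simulate_dataset(const_deme(n_ref = 10), 20, 10, 1, seed = 1),
               "individuals at sampling time")
})

test_that("serial founder preset has the found-and-grow backbone", {
  sc <- serial_founder_preset(2, founder_fraction = 0.05, interval = 0.2,
                              migration = 0)
  expect_equal(nrow(sc$events), 1)
  expect_equal(sc$events$type, "founding")
  expect_equal(sc$events$time, 0.2)
  # colony epoch shrinks back to s * parent size at the founding
  col <- sc$epochs[sc$epochs$deme == "deme2", ]
  expect_equal(col$nu1, 0.05)
  expect_error(serial_founder_preset(2, founder_fraction = 1.2), "founder_fraction")
  expect_error(serial_founder_preset(1), "n_demes")
  # coordinates laid out on a line
  expect_equal(sc$coords$lon, c(0, 12))
})

test_that("founder chains lose diversity and reverse Tajima's D sign", {
  # single founder event: bottleneck + growth raises D relative to the
  # growing-only scenario; diversity decreases along the chain
  sc3 <- serial_founder_preset(3, founder_fraction = 0.02, interval = 0.15,
                               migration = 0)
  pis <- matrix(NA_real_, 10, 3)
  for (r in 1:10) {
    ds <- simulate_dataset(sc3, c(6, 6, 6), n_loci = 300, theta = 1,
                           seed = 100 + r)
    div <- diversity(ds$gm, ds$popmap)
    pis[r, ] <- div$pi[match(paste0("deme", 1:3), div$pop)]
  }
  expect_gt(mean(pis[, 1] > pis[, 2]), 0.8)
  expect_gt(mean(pis[, 2] > pis[, 3]), 0.8)
})

test_that("dataset writer emits the full provenance bundle", {
  sc <- serial_founder_preset(2, migration = 0)
  ds <- simulate_dataset(sc, c(4, 4), n_loci = 100, theta = 1, seed = 11)
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  expect_true(all(file.exists(file.path(
    dir, c("genotypes.vcf", "popmap.tsv", "outgroup.tsv", "scenario.json")))))
  back <- read_vcf(file.path(dir, "genotypes.vcf"))
  expect_equal(back$calls, ds$gm$calls, ignore_attr = TRUE)
  js <- jsonlite::read_json(file.path(dir, "scenario.json"))
  expect_equal(js$seed, 11)
})

test_that("cross-validation: two-deme split spectrum agrees with msprime", {
  # Frozen oracle from the independent coalescent simulator msprime
  # (v1.4.2, 100,000 replicates): two constant-size demes splitting at
  # T = 0.4 (2N-generation units), samples (6, 6) haploid copies, no
  # migration; per-unit-theta branch-length spectrum (row = deme A count).
  oracle <- matrix(c(
    0,       0.80669, 0.32158, 0.16197, 0.09178, 0.05070, 0.03394,
    0.80743, 0.04821, 0.04062, 0.03328, 0.02635, 0.02105, 0.02245,
    0.32015, 0.04041, 0.03459, 0.03083, 0.02621, 0.02143, 0.02674,
    0.16558, 0.03386, 0.03035, 0.02659, 0.02434, 0.02184, 0.03239,
    0.09046, 0.02703, 0.02633, 0.02481, 0.02263, 0.02142, 0.03740,
    0.05099, 0.02054, 0.02105, 0.02166, 0.02155, 0.02101, 0.04176,
    0.03378, 0.02186, 0.02729, 0.03075, 0.03825, 0.04197, 0),
    nrow = 7, byrow = TRUE)
  sc <- demographic_scenario(
    dplyr::bind_rows(
      tibble::tibble(deme = "A", t0 = 0, t1 = Inf, nu0 = 1, nu1 = 1,
                     curve = "constant"),
      tibble::tibble(deme = "B", t0 = 0, t1 = 0.4, nu0 = 1, nu1 = 1,
                     curve = "constant")),
    events = tibble::tibble(time = 0.4, type = "founding", source = "A",
                            target = "B", fraction = 0.5),
    labels = c("A", "B"))
  s <- simulate_expected_sfs(sc, c(6, 6), n_reps = 20000, seed = 77)
  se <- pmax(attr(s, "se"), 1e-4)
  z <- abs(s$counts - oracle) / se
  expect_lt(max(z[!s$mask]), 4)
  # total tree mass also agrees
  expect_equal(sum(s$counts[!s$mask]), sum(oracle), tolerance = 0.02)
})
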