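#' Per-population diversity statistics
#'
#' For each population: mean per-SNP pairwise diversity
#' `pi_hat = (2n / (2n - 1)) * 2 p (1 - p)` with `n` the diploids genotyped
#' at the locus, mean observed heterozygosity, and the mean within-sample
#' heterozygous/homozygous locus ratio. All statistics are averages over the
#' SNP loci of the matrix (per-SNP scale, not per-base).
#'
#' @param gm a [genotype_matrix()].
#' @param popmap popmap tibble (`sample`, `pop`).
#' @return tibble `pop`, `n_samples`, `pi`, `h_o`, `het_hom`.
#' @export
diversity <- function(gm, popmap) {
  pops <- unique(popmap$pop[popmap$sample %in% gm$sample_ids])
  rows <- lapply(pops, function(p) {
    rows_idx <- match(popmap$sample[popmap$pop == p], gm$sample_ids)
    rows_idx <- rows_idx[!is.na(rows_idx)]
    g <- gm$calls[rows_idx, , drop = FALSE]
    n_obs <- colSums(!is.na(g))
    if (all(n_obs == 0))
      stop("population '", p, "' has no non-missing calls")
    ok <- n_obs > 0
    p_hat <- colSums(g, na.rm = TRUE)[ok] / (2 * n_obs[ok])
    n <- n_obs[ok]
    pi_l <- ifelse(n > 1, (2 * n) / (2 * n - 1) * 2 * p_hat * (1 - p_hat),
                   NA_real_)
    ho_l <- colMeans(g == 1, na.rm = TRUE)[ok]
    het <- rowSums(g == 1, na.rm = TRUE)
    hom <- rowSums(g != 1, na.rm = TRUE)
    tibble(pop = p, n_samples = length(rows_idx),
           pi = mean(pi_l, na.rm = TRUE),
           h_o = mean(ho_l, na.rm = TRUE),
           het_hom = mean(ifelse(hom > 0, het / hom, NA_real_), na.rm = TRUE))
  })
  dplyr::bind_rows(rows)
}

tajima_constants <- function(n) {
  i <- seq_len(n - 1)
  a1 <- sum(1 / i)
  a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1))
  b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  list(a1 = a1, a2 = a2, b1 = b1, b2 = b2, c1 = c1, c2 = c2,
       e1 = c1 / a1, e2 = c2 / (a1^2 + a2))
}

#' Tajima's D from a one-population spectrum
#'
#' `D = (pi_hat - S / a1) / sqrt(e1 S + e2 S (S - 1))` with the 1989
#' normalizing constants computed from the gene-copy sample size, and
#' `pi_hat` read off the spectrum as `sum xi_i i (n - i) / choose(n, 2)`.
#' Works on folded spectra too (the pairwise-difference weights are
#' symmetric under i -> n - i).
#'
#' @param sfs a one-population [joint_sfs()].
#' @return list with `D`, `S`, `n` and the intermediate constants.
#' @export
tajimas_d <- function(sfs) {
  if (length(sfs$sizes) != 1) stop("tajimas_d requires a 1-population SFS")
  n <- sfs$sizes[1]
  xi <- sfs$counts[, 1]
  xi[sfs$mask[, 1]] <- 0
  S <- sum(xi)
  if (S < 1) stop("Tajima's D is undefined for S = 0", call. = FALSE)
  i <- 0:n
  pi_hat <- sum(xi * i * (n - i)) / choose(n, 2)
  k <- tajima_constants(n)
  D <- (pi_hat - S / k$a1) / sqrt(k$e1 * S + k$e2 * S * (S - 1))
  c(list(D = D, S = S, n = n, pi = pi_hat), k)
}

# Weir & Cockerham (1984) per-locus variance components for two populations.
# Returns per-locus a (among), b (within-population between-individual) and
# c (within-individual) from allele frequencies and heterozygote counts.
wc_components <- function(g1, g2) {
  n1 <- colSums(!is.na(g1)); n2 <- colSums(!is.na(g2))
  usable <- n1 >= 1 & n2 >= 1
  r <- 2
  n1 <- n1[usable]; n2 <- n2[usable]
  p1 <- colSums(g1, na.rm = TRUE)[usable] / (2 * n1)
  p2 <- colSums(g2, na.rm = TRUE)[usable] / (2 * n2)
  h1 <- colMeans(g1 == 1, na.rm = TRUE)[usable]
  h2 <- colMeans(g2 == 1, na.rm = TRUE)[usable]
  nbar <- (n1 + n2) / r
  nc <- (r * nbar - (n1^2 + n2^2) / (r * nbar)) / (r - 1)
  pbar <- (n1 * p1 + n2 * p2) / (r * nbar)
  s2 <- (n1 * (p1 - pbar)^2 + n2 * (p2 - pbar)^2) / ((r - 1) * nbar)
  hbar <- (n1 * h1 + n2 * h2) / (r * nbar)
  a <- nbar / nc *
    (s2 - (pbar * (1 - pbar) - (r - 1) / r * s2 - hbar / 4) / (nbar - 1))
  b <- nbar / (nbar - 1) *
    (pbar * (1 - pbar) - (r - 1) / r * s2 - (2 * nbar - 1) / (4 * nbar) * hbar)
  cc <- hbar / 2
  list(a = a, b = b, c = cc)
}

#' Weir-Cockerham F_ST between two populations
#'
#' Multi-locus theta: per-locus variance components a/b/c per Weir &
#' Cockerham (1984), combined as a ratio of sums. Loci are screened at a
#' pooled-sample minor allele frequency of `maf` first.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap popmap tibble.
#' @param pop_a,pop_b population labels.
#' @param maf pooled minor-allele-frequency cutoff applied before
#'   estimation (set 0 to disable).
#' @return theta (scalar).
#' @export
wc_fst <- function(gm, popmap, pop_a, pop_b, maf = 0.05) {
  ia <- match(popmap$sample[popmap$pop == pop_a], gm$sample_ids)
  ib <- match(popmap$sample[popmap$pop == pop_b], gm$sample_ids)
  ia <- ia[!is.na(ia)]; ib <- ib[!is.na(ib)]
  if (length(ia) < 2 || length(ib) < 2)
    stop("both populations need >= 2 genotyped samples")
  pooled <- gm$calls[c(ia, ib), , drop = FALSE]
  keep <- rep(TRUE, ncol(pooled))
  if (maf > 0) {
    mafs <- locus_maf(pooled)
    keep <- !is.na(mafs) & mafs >= maf
  }
  if (!any(keep)) stop("no loci pass the MAF filter")
  comp <- wc_components(gm$calls[ia, keep, drop = FALSE],
                        gm$calls[ib, keep, drop = FALSE])
  sum(comp$a) / sum(comp$a + comp$b + comp$c)
}

#' Permutation significance for F_ST
#'
#' Individuals are randomly reassigned between the two populations (group
#' sizes preserved) `n_perm` times; the p-value is
#' `(1 + #\{theta_perm >= theta_obs\}) / (n_perm + 1)`.
#'
#' @inheritParams wc_fst
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return tibble `theta`, `p`, `n_perm`, `seed`.
#' @export
fst_permutation_test <- function(gm, popmap, pop_a, pop_b, n_perm = 1000,
                                 seed = 1, maf = 0.05) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  ia <- match(popmap$sample[popmap$pop == pop_a], gm$sample_ids)
  ib <- match(popmap$sample[popmap$pop == pop_b], gm$sample_ids)
  ia <- ia[!is.na(ia)]; ib <- ib[!is.na(ib)]
  if (length(ia) < 2 || length(ib) < 2)
    stop("both populations need >= 2 genotyped samples")
  pooled_idx <- c(ia, ib)
  pooled <- gm$calls[pooled_idx, , drop = FALSE]
  keep <- rep(TRUE, ncol(pooled))
  if (maf > 0) {
    mafs <- locus_maf(pooled)
    keep <- !is.na(mafs) & mafs >= maf
  }
  calls <- pooled[, keep, drop = FALSE]
  na <- length(ia)
  theta_of <- function(rows_a) {
    comp <- wc_components(calls[rows_a, , drop = FALSE],
                          calls[-rows_a, , drop = FALSE])
    sum(comp$a) / sum(comp$a + comp$b + comp$c)
  }
  obs <- theta_of(seq_len(na))
  n_tot <- nrow(calls)
  perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) theta_of(sample.int(n_tot, na)),
           numeric(1))
  })
  tibble(theta = obs,
         p = (1 + sum(perm >= obs)) / (n_perm + 1),
         n_perm = n_perm, seed = seed)
}

#' Directionality index psi
#'
#' Mean derived-allele frequency difference at shared polymorphisms between
#' two equally sized populations:
#' `psi_{A->B} = sum f_ij (j/n - i/n) / sum f_ij` over unmasked cells with
#' the derived allele present in both populations (i, j >= 1) and not fixed
#' in both. Positive values indicate expansion from A toward B (the colony
#' carries shared derived alleles at higher frequency).
#'
#' @param sfs a polarized two-population [joint_sfs()] with equal sizes,
#'   ordered (A, B).
#' @return tibble `from`, `to`, `psi`, `n_sites`.
#' @export
psi <- function(sfs) {
  if (length(sfs$sizes) != 2) stop("psi requires a 2-population SFS")
  if (!sfs$polarized) stop("psi requires a polarized spectrum")
  if (sfs$sizes[1] != sfs$sizes[2])
    stop("psi requires equal sample sizes; project the spectrum first")
  n <- sfs$sizes[1]
  i <- matrix(0:n, n + 1, n + 1)
  j <- t(i)
  use <- i >= 1 & j >= 1 & !(i == n & j == n) & !sfs$mask
  tot <- sum(sfs$counts[use])
  if (tot == 0)
    stop("psi is undefined: no shared-derived sites", call. = FALSE)
  val <- sum(sfs$counts[use] * (j[use] / n - i[use] / n)) / tot
  tibble(from = sfs$pops[1], to = sfs$pops[2], psi = val, n_sites = tot)
}

#' Evanno's delta-K
#'
#' Given per-K, per-replicate clustering log-likelihoods,
#' `deltaK(K) = |mean L(K+1) - 2 mean L(K) + mean L(K-1)| / sd(L(K))`.
#' Boundary K values and K with zero replicate variance get `NA` with the
#' `undefined` flag set (an undefined delta-K, not a numerical accident).
#'
#' @param table tibble with columns `k`, `rep`, `loglik`; K values must be
#'   consecutive integers with >= 2 replicates each.
#' @return tibble `k`, `mean_loglik`, `sd_loglik`, `delta_k`, `undefined`.
#' @export
evanno_delta_k <- function(table) {
  table <- as_tibble(table)
  ks <- sort(unique(table$k))
  if (length(ks) < 3) stop("need >= 3 consecutive K values")
  if (!all(diff(ks) == 1)) stop("K grid must be consecutive integers")
  agg <- table |>
    dplyr::group_by(.data$k) |>
    dplyr::summarise(mean_loglik = mean(.data$loglik),
                     sd_loglik = sd(.data$loglik),
                     n_rep = dplyr::n(), .groups = "drop") |>
    dplyr::arrange(.data$k)
  if (any(agg$n_rep < 2)) stop("each K needs >= 2 replicates")
  m <- agg$mean_loglik
  second <- c(NA, abs(diff(m, differences = 2)), NA)
  delta <- second / agg$sd_loglik
  undef <- is.na(second) | agg$sd_loglik == 0
  delta[agg$sd_loglik == 0] <- NA_real_
  tibble(k = agg$k, mean_loglik = m, sd_loglik = agg$sd_loglik,
         delta_k = delta, undefined = undef)
}
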