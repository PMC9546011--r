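#' Exact test of Hardy-Weinberg proportions
#'
#' Two-sided exact test for a biallelic locus: conditional on the observed
#' allele counts, the p-value is the summed probability of every
#' heterozygote configuration no more probable than the observed one
#' (Levene's conditional distribution, evaluated with the stable ratio
#' recurrence). Used to screen genotype panels for systematic departures
#' from random mating.
#'
#' @param n_hom_ref count of reference-homozygous individuals.
#' @param n_het count of heterozygous individuals.
#' @param n_hom_alt count of alternative-homozygous individuals.
#' @return exact p-value in (0, 1].
#' @export
hwe_exact_test <- function(n_hom_ref, n_het, n_hom_alt) {
  stopifnot(n_hom_ref >= 0, n_het >= 0, n_hom_alt >= 0)
  n <- n_hom_ref + n_het + n_hom_alt
  if (n == 0) stop("at least one genotype count must be non-zero")
  n_rare <- 2 * min(n_hom_ref, n_hom_alt) + n_het
  # admissible heterozygote counts share the parity of n_rare
  h_min <- if (n_rare > n) 2 * n_rare - 2 * n else n_rare %% 2
  h_max <- min(n_rare, 2 * n - n_rare)
  if (h_max < h_min) h_max <- h_min
  hs <- seq(h_min, h_max, by = 2)
  # unnormalized probabilities via the ratio recurrence:
  # P(h+2)/P(h) = 4 * n_rr(h) * n_cc(h) / ((h+2) * (h+1))
  # where n_rr = (n_rare - h)/2 rare homozygotes, n_cc common homozygotes.
  lp <- numeric(length(hs))
  for (i in seq_along(hs)[-1]) {
    h <- hs[i - 1]
    n_rr <- (n_rare - h) / 2
    n_cc <- n - h - n_rr
    lp[i] <- lp[i - 1] + log(4 * n_rr * n_cc) - log((h + 2) * (h + 1))
  }
  p <- exp(lp - max(lp))
  p <- p / sum(p)
  obs <- match(n_het, hs)
  if (is.na(obs)) stop("genotype counts inconsistent with allele counts")
  min(1, sum(p[p <= p[obs] * (1 + 1e-12)]))
}

#' Hardy-Weinberg exact p-values for every locus of a genotype matrix
#'
#' @param gm a [genotype_matrix()].
#' @return tibble `chrom`, `pos`, `p` (NA where all calls are missing).
#' @export
hwe_scan <- function(gm) {
  p <- apply(gm$calls, 2, function(g) {
    g <- g[!is.na(g)]
    if (length(g) == 0) return(NA_real_)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  })
  tibble(chrom = gm$loci$chrom, pos = gm$loci$pos, p = p)
}
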