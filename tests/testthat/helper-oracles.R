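# Independent oracles used across the suite. Each deliberately takes a
# different computational route from the package implementation.

# --- Hardy-Weinberg exact test by direct multinomial enumeration ---------
hwe_oracle <- function(n_hom_ref, n_het, n_hom_alt) {
  n <- n_hom_ref + n_het + n_hom_alt
  n_a <- 2 * n_hom_ref + n_het # reference allele copies
  # enumerate every genotype triple with the same n and allele counts
  probs <- c()
  hs <- c()
  for (h in 0:n) {
    n_rr <- (n_a - h) / 2
    if (n_rr != round(n_rr) || n_rr < 0) next
    n_aa <- n - h - n_rr
    if (n_aa < 0) next
    lp <- lgamma(n + 1) - lgamma(n_rr + 1) - lgamma(h + 1) -
      lgamma(n_aa + 1) + h * log(2) +
      lgamma(n_a + 1) + lgamma(2 * n - n_a + 1) - lgamma(2 * n + 1)
    probs <- c(probs, exp(lp))
    hs <- c(hs, h)
  }
  probs <- probs / sum(probs)
  p_obs <- probs[hs == n_het]
  sum(probs[probs <= p_obs * (1 + 1e-12)])
}

# --- Tajima's D re-implemented from the 1989 definitions ----------------
tajima_oracle <- function(xi, n) {
  i <- seq_len(n - 1)
  S <- sum(xi[i + 1])
  stopifnot(S >= 1)
  pi_hat <- sum(xi[i + 1] * i * (n - i)) * 2 / (n * (n - 1))
  a1 <- sum(1 / i); a2 <- sum(1 / i^2)
  b1 <- (n + 1) / (3 * (n - 1)); b2 <- 2 * (n^2 + n + 3) / (9 * n * (n - 1))
  c1 <- b1 - 1 / a1
  c2 <- b2 - (n + 2) / (a1 * n) + a2 / a1^2
  e1 <- c1 / a1; e2 <- c2 / (a1^2 + a2)
  (pi_hat - S / a1) / sqrt(e1 * S + e2 * S * (S - 1))
}

# --- Weir-Cockerham theta via a literal nested ANOVA --------------------
# Builds the gamete-level indicator data and computes observed mean squares
# (populations / individuals / gametes), then the WC variance components
# sigma2_P = (MSP - MSI) / (2 n_c), sigma2_I = (MSI - MSG) / 2,
# sigma2_G = MSG. Computationally independent of the closed-form route.
fst_oracle <- function(g1, g2) {
  num <- 0; den <- 0
  for (l in seq_len(ncol(g1))) {
    x1 <- g1[, l]; x2 <- g2[, l]
    x1 <- x1[!is.na(x1)]; x2 <- x2[!is.na(x2)]
    n1 <- length(x1); n2 <- length(x2)
    if (n1 < 1 || n2 < 1) next
    # gamete indicators: genotype 0 -> (0,0), 1 -> (0,1), 2 -> (1,1)
    gam <- function(x) t(vapply(x, function(g)
      switch(g + 1, c(0, 0), c(0, 1), c(1, 1)), numeric(2)))
    y1 <- gam(x1); y2 <- gam(x2)
    ybar_ind <- c(rowMeans(y1), rowMeans(y2))
    pop_of <- rep(1:2, c(n1, n2))
    ybar_pop <- c(mean(y1), mean(y2))
    ntot <- n1 + n2
    ybar_tot <- sum(c(y1, y2)) / (2 * ntot)
    ssg <- sum((rbind(y1, y2) - ybar_ind)^2)
    ssi <- sum(2 * (ybar_ind - ybar_pop[pop_of])^2)
    ssp <- 2 * n1 * (ybar_pop[1] - ybar_tot)^2 +
      2 * n2 * (ybar_pop[2] - ybar_tot)^2
    msg <- ssg / ntot
    msi <- ssi / (ntot - 2)
    msp <- ssp / 1
    nc <- (ntot - (n1^2 + n2^2) / ntot) / 1
    a <- (msp - msi) / (2 * nc)
    b <- (msi - msg) / 2
    cc <- msg
    num <- num + a
    den <- den + a + b + cc
  }
  num / den
}

# --- hypergeometric projection by exhaustive subsample enumeration ------
# expected projected spectrum computed by enumerating every way of drawing
# m copies out of n given i derived, via dhyper on integer draws
project_oracle_1d <- function(xi, n, m) {
  out <- numeric(m + 1)
  for (i in 0:n) {
    for (j in 0:m) {
      w <- choose(i, j) * choose(n - i, m - j) / choose(n, m)
      out[j + 1] <- out[j + 1] + xi[i + 1] * w
    }
  }
  out
}

# --- small genotype matrix builders -------------------------------------
toy_gm <- function(calls, chrom = NULL, pos = NULL, ref = "A", alt = "T") {
  calls <- as.matrix(calls)
  L <- ncol(calls)
  tibble::tibble(
    chrom = if (is.null(chrom)) rep("chr1", L) else chrom,
    pos = if (is.null(pos)) seq_len(L) * 1000L else as.integer(pos),
    ref = rep_len(ref, L), alt = rep_len(alt, L)) -> loci
  pacifex::genotype_matrix(calls, loci)
}

# write a small VCF by hand (text fixture built in code)
write_toy_vcf <- function(path, samples, records) {
  hdr <- c("##fileformat=VCFv4.2",
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", samples), collapse = "\t"))
  writeLines(c(hdr, records), path)
  path
}
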