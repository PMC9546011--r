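#' Remove poorly genotyped individuals
#'
#' Drops samples genotyped at fewer than `min_rate` of loci, the standard
#' call-rate filter applied before computing diversity statistics.
#'
#' @param gm a [genotype_matrix()].
#' @param min_rate minimum fraction of non-missing loci per sample.
#' @return list with elements `gm` (filtered matrix) and `report`.
#' @export
filter_individuals_by_call_rate <- function(gm, min_rate = 0.75) {
  stopifnot(min_rate >= 0, min_rate <= 1)
  n_loci <- ncol(gm$calls)
  rate <- if (n_loci == 0) rep(1, nrow(gm$calls))
          else rowMeans(!is.na(gm$calls))
  keep <- rate >= min_rate
  list(gm = gm_subset(gm, samples = keep),
       report = filter_report("call_rate", gm$sample_ids[!keep], min_rate))
}

# minor allele frequency per locus over observed gene copies
locus_maf <- function(calls) {
  alt <- colSums(calls, na.rm = TRUE)
  ncopies <- 2 * colSums(!is.na(calls))
  p <- ifelse(ncopies > 0, alt / ncopies, NA_real_)
  pmin(p, 1 - p)
}

#' Filter loci by minor allele frequency
#'
#' Retains loci whose sample minor-allele frequency, computed over observed
#' gene copies only, is at least `min_maf` (inclusive threshold). Loci with
#' all calls missing are removed and flagged.
#'
#' @inheritParams filter_individuals_by_call_rate
#' @param min_maf minimum minor allele frequency.
#' @export
filter_loci_by_maf <- function(gm, min_maf = 0.05) {
  if (ncol(gm$calls) == 0) stop("empty genotype matrix")
  maf <- locus_maf(gm$calls)
  all_missing <- is.na(maf)
  keep <- !all_missing & maf >= min_maf
  removed <- paste(gm$loci$chrom, gm$loci$pos, sep = ":")[!keep]
  rep <- filter_report("maf", removed, min_maf)
  rep$all_missing <- paste(gm$loci$chrom, gm$loci$pos, sep = ":")[all_missing]
  list(gm = gm_subset(gm, loci = keep), report = rep)
}

#' Thin loci by physical distance
#'
#' Randomly subsamples loci so that no two retained loci on the same
#' chromosome lie within `min_bp` of each other: loci are visited in a
#' seeded random order and accepted when no previously accepted locus on the
#' chromosome conflicts. This is the linkage-thinning step applied before
#' building site frequency spectra.
#'
#' @inheritParams filter_individuals_by_call_rate
#' @param min_bp minimum pairwise distance in base pairs.
#' @param seed integer seed making the subsample reproducible.
#' @export
thin_loci_by_distance <- function(gm, min_bp = 10000, seed = 1) {
  stopifnot(min_bp > 0)
  n <- ncol(gm$calls)
  if (n == 0) return(list(gm = gm, report = filter_report("thin", character(), min_bp, seed)))
  ord <- withr::with_seed(seed, sample.int(n))
  keep <- logical(n)
  acc_pos <- split(numeric(0), character(0))
  for (i in ord) {
    ch <- gm$loci$chrom[i]
    pos <- gm$loci$pos[i]
    prev <- acc_pos[[ch]]
    if (is.null(prev) || all(abs(prev - pos) >= min_bp)) {
      keep[i] <- TRUE
      acc_pos[[ch]] <- c(prev, pos)
    }
  }
  removed <- paste(gm$loci$chrom, gm$loci$pos, sep = ":")[!keep]
  list(gm = gm_subset(gm, loci = keep),
       report = filter_report("thin", removed, min_bp, seed))
}
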