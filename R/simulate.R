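#' Expected SFS by coalescent branch-length accumulation
#'
#' Simulates `n_reps` genealogies of the requested sample under a
#' [demographic_scenario()] and averages, per joint descendant-count cell,
#' the branch length subtending that configuration. Divided by two this is
#' the expected spectrum per unit theta (`theta = 4 N_ref mu L`), since a
#' branch of length t (in 2 N_ref generations) carries `t * theta / 2`
#' expected mutations.
#'
#' @param scenario a [demographic_scenario()].
#' @param sample_sizes gene copies per sampled deme (length 1 or 2).
#' @param demes labels of the sampled demes (default: first 1 or 2 demes).
#' @param n_reps genealogy replicates.
#' @param seed RNG seed.
#' @return a [joint_sfs()] (per-unit-theta) with an `se` attribute.
#' @export
simulate_expected_sfs <- function(scenario, sample_sizes, demes = NULL,
                                  n_reps = 5000, seed = 1) {
  stopifnot(length(sample_sizes) %in% 1:2, n_reps >= 1)
  if (is.null(demes)) demes <- scenario$labels[seq_along(sample_sizes)]
  norm <- normalize_scenario(scenario)
  deme_of_copy <- rep(norm$idx[demes], sample_sizes)
  pop_of_copy <- rep(seq_along(sample_sizes) - 1L, sample_sizes)
  n1 <- sample_sizes[1]
  n2 <- if (length(sample_sizes) == 2) sample_sizes[2] else 0L
  res <- withr::with_seed(seed,
    cpp_branch_sfs(norm$phases, norm$events, norm$n_demes,
                   as.integer(deme_of_copy), as.integer(pop_of_copy),
                   as.integer(n1), as.integer(n2), as.integer(n_reps)))
  out <- joint_sfs(res$mean / 2, sample_sizes, pops = demes,
                   polarized = TRUE)
  attr(out, "se") <- res$se / 2 # cpp already returns the SE of the mean
  out
}

#' Simulate a complete synthetic dataset
#'
#' Independent genealogies per locus; mutations placed by a Poisson process
#' on branches under the infinite-sites model (by default one retained SNP
#' per locus, RAD-like); genotypes formed by pairing consecutive gene
#' copies into diploids; uniform random missingness. Returns everything the
#' downstream pipeline consumes: genotype matrix, population map with
#' coordinates, true ancestral (outgroup) states and full provenance.
#'
#' @param scenario a [demographic_scenario()].
#' @param n_per_deme named (or ordered) diploid sample sizes per deme.
#' @param n_loci number of loci.
#' @param theta per-locus scaled mutation rate `4 N_ref mu L`.
#' @param missing_rate per-genotype missing probability.
#' @param one_snp_per_locus retain a single SNP per polymorphic locus?
#' @param seed RNG seed; the dataset is reproducible from
#'   (scenario, arguments, seed).
#' @return list of class `synthetic_dataset` with elements `gm`, `popmap`,
#'   `outgroup`, `scenario`, `seed`.
#' @export
simulate_dataset <- function(scenario, n_per_deme, n_loci, theta = 1,
                             missing_rate = 0, one_snp_per_locus = TRUE,
                             seed = 1) {
  stopifnot(n_loci >= 1, theta >= 0, missing_rate >= 0, missing_rate < 1)
  labels <- scenario$labels
  if (is.null(names(n_per_deme))) {
    stopifnot(length(n_per_deme) <= length(labels))
    n_per_deme <- setNames(n_per_deme, labels[seq_along(n_per_deme)])
  }
  sampled <- names(n_per_deme)[n_per_deme > 0]
  # capacity check against present-day deme sizes in individuals
  for (d in sampled) {
    cap <- scenario_size_at(scenario, d, 0) * scenario$n_ref
    if (n_per_deme[[d]] > cap)
      stop("deme ", d, " holds ~", round(cap),
           " individuals at sampling time; ", n_per_deme[[d]], " requested")
  }
  norm <- normalize_scenario(scenario)
  deme_of_copy <- rep(norm$idx[sampled], 2 * unlist(n_per_deme[sampled]))
  n_copies <- length(deme_of_copy)

  loci <- withr::with_seed(seed,
    cpp_sim_loci(norm$phases, norm$events, norm$n_demes,
                 as.integer(deme_of_copy), theta, as.integer(n_loci),
                 isTRUE(one_snp_per_locus)))

  withr::with_seed(seed + 1L, {
    snp_list <- list()
    locus_ids <- integer()
    for (l in seq_along(loci)) {
      m <- loci[[l]]
      if (nrow(m) == 0) next
      poly <- rowSums(m) > 0 & rowSums(m) < ncol(m)
      m <- m[poly, , drop = FALSE]
      if (nrow(m) == 0) next
      snp_list[[length(snp_list) + 1]] <- m
      locus_ids <- c(locus_ids, rep(l, nrow(m)))
    }
    samples <- unlist(lapply(sampled, function(d)
      sprintf("%s_%02d", d, seq_len(n_per_deme[[d]]))))
    if (length(snp_list) == 0) {
      gm <- genotype_matrix(
        matrix(integer(), length(samples), 0,
               dimnames = list(samples, NULL)),
        tibble(chrom = character(), pos = integer(), ref = character(),
               alt = character()))
      outgroup <- tibble(chrom = character(), pos = integer(),
                         allele = character())
    } else {
      derived <- do.call(rbind, snp_list)
      # diploid genotypes: copies (2i-1, 2i) belong to individual i
      odd <- seq(1, n_copies, by = 2)
      geno <- derived[, odd, drop = FALSE] + derived[, odd + 1, drop = FALSE]
      n_snp <- nrow(geno)
      # locus l sits at position l * 5e4; SNPs within a 150 bp RAD window
      offset <- stats::ave(seq_len(n_snp), locus_ids, FUN = seq_along)
      pos <- as.integer(locus_ids * 5e4 + offset)
      bases <- c("A", "C", "G", "T")
      anc <- sample(bases, n_snp, replace = TRUE)
      der <- vapply(anc, function(b) sample(setdiff(bases, b), 1), "")
      # the reference genome is not always the ancestral state
      ref_is_anc <- runif(n_snp) < 0.5
      ref <- ifelse(ref_is_anc, anc, der)
      alt <- ifelse(ref_is_anc, der, anc)
      calls <- t(geno)
      calls[, !ref_is_anc] <- 2L - calls[, !ref_is_anc, drop = FALSE]
      if (missing_rate > 0)
        calls[runif(length(calls)) < missing_rate] <- NA_integer_
      rownames(calls) <- samples
      gm <- genotype_matrix(calls,
                            tibble(chrom = "chr1", pos = pos,
                                   ref = ref, alt = alt, anc = anc))
      outgroup <- tibble(chrom = "chr1", pos = pos, allele = anc)
    }
    popmap <- tibble(
      sample = samples,
      pop = rep(sampled, unlist(n_per_deme[sampled])))
    if (!is.null(scenario$coords)) {
      cc <- scenario$coords
      popmap$lat <- cc$lat[match(popmap$pop, cc$deme)]
      popmap$lon <- cc$lon[match(popmap$pop, cc$deme)]
      # jitter samples slightly around the deme location so individual
      # geographic distances are defined within demes
      popmap$lat <- popmap$lat + runif(nrow(popmap), -0.5, 0.5)
      popmap$lon <- popmap$lon + runif(nrow(popmap), -0.5, 0.5)
    }
    structure(list(gm = gm, popmap = popmap, outgroup = outgroup,
                   scenario = scenario, seed = seed),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("<synthetic_dataset> ", nrow(x$gm$calls), " samples, ",
      ncol(x$gm$calls), " SNPs, ", length(unique(x$popmap$pop)),
      " population(s); seed ", x$seed, "\n", sep = "")
  invisible(x)
}

#' Write a synthetic dataset to disk
#'
#' Emits the VCF, popmap TSV, outgroup TSV and a scenario/seed provenance
#' JSON under `dir`.
#'
#' @param ds a `synthetic_dataset`.
#' @param dir output directory (created if needed).
#' @export
write_dataset <- function(ds, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_vcf(ds$gm, file.path(dir, "genotypes.vcf"))
  write_popmap(ds$popmap, file.path(dir, "popmap.tsv"))
  utils::write.table(ds$outgroup, file.path(dir, "outgroup.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(seed = ds$seed, n_ref = ds$scenario$n_ref,
         labels = ds$scenario$labels,
         epochs = ds$scenario$epochs, events = ds$scenario$events,
         migration = ds$scenario$migration),
    file.path(dir, "scenario.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}
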