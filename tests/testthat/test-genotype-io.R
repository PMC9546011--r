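test_that("read_vcf transcribes a hand-written VCF exactly", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, c("S1", "S2"), c(
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/0\t0/1",
    "chr1\t250\t.\tC\tG\t.\tPASS\t.\tGT\t1/1\t0/0",
    "chr2\t50\t.\tG\tA\t.\tPASS\t.\tGT\t./.\t1/1"))
  gm <- read_vcf(path)
  expect_equal(dim(gm$calls), c(2L, 3L))
  expect_equal(unname(gm$calls[1, ]), c(0L, 2L, NA))
  expect_equal(unname(gm$calls[2, ]), c(1L, 0L, 2L))
  expect_equal(gm$loci$pos, c(100L, 250L, 50L))
  expect_equal(gm$loci$ref, c("A", "C", "G"))
  expect_equal(gm$sample_ids, c("S1", "S2"))
})

test_that("multi-allelic records are skipped and empty VCFs error", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, "S1", c(
    "chr1\t1\t.\tA\tT,C\t.\tPASS\t.\tGT\t0/1",
    "chr1\t9\t.\tA\tT\t.\tPASS\t.\tGT\t0/1"))
  expect_message(gm <- read_vcf(path), "skipping")
  expect_equal(ncol(gm$calls), 1L)

  path2 <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path2, "S1", "chr1\t1\t.\tA\tT,C\t.\tPASS\t.\tGT\t0/1")
  expect_error(read_vcf(path2), "no biallelic")
})

test_that("write_vcf / read_vcf round-trip preserves calls and positions", {
  set.seed(7)
  calls <- matrix(sample(c(0:2, NA), 60, replace = TRUE), nrow = 5)
  gm <- toy_gm(calls, chrom = rep(c("chr1", "chr2"), each = 6),
               pos = rep(seq_len(6) * 500, 2))
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm, path)
  back <- read_vcf(path)
  expect_equal(back$calls, gm$calls, ignore_attr = TRUE)
  expect_equal(back$loci$chrom, gm$loci$chrom)
  expect_equal(back$loci$pos, gm$loci$pos)
  # missing cells round-trip as ./.
  expect_true(any(grepl("\\./\\.", readLines(path))))
  # empty matrix -> header-only VCF, still re-readable structure
  gm0 <- genotype_matrix(matrix(integer(), 2, 0,
                                dimnames = list(c("a", "b"), NULL)),
                         tibble::tibble(chrom = character(),
                                        pos = integer(), ref = character(),
                                        alt = character()))
  path0 <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(gm0, path0)
  expect_equal(length(readLines(path0)), 3L) # two meta lines + column header
})

test_that("genotype matrix invariants are enforced", {
  expect_error(toy_gm(matrix(3L, 1, 1)), "0, 1 or 2")
  expect_error(toy_gm(matrix(0L, 1, 2), pos = c(10, 10)), "unique")
  expect_error(toy_gm(matrix(0L, 1, 1), pos = -5), "positive")
})

test_that("call-rate filter removes exactly the samples below threshold", {
  # call rates 0.80, 0.74..., 1.00 across 50 loci
  calls <- rbind(c(rep(0L, 40), rep(NA, 10)),
                 c(rep(1L, 37), rep(NA, 13)),
                 rep(2L, 50))
  rownames(calls) <- c("hi", "lo", "full")
  gm <- toy_gm(calls)
  res <- filter_individuals_by_call_rate(gm, 0.75)
  expect_equal(res$gm$sample_ids, c("hi", "full"))
  expect_equal(res$report$removed, "lo")
  # min_rate 0 keeps everything; complete data is identity
  expect_equal(filter_individuals_by_call_rate(gm, 0)$gm$sample_ids,
               gm$sample_ids)
  full <- toy_gm(matrix(1L, 3, 4))
  expect_equal(filter_individuals_by_call_rate(full, 0.75)$gm$calls,
               full$calls)
})

test_that("MAF filter uses observed gene copies and an inclusive threshold", {
  # 10 diploids, 1 heterozygote -> freq 0.05 exactly: retained at >= 0.05
  g1 <- c(1L, rep(0L, 9))
  # monomorphic locus; freq 2/50 = 0.04 -> removed
  g3 <- c(2L, rep(0L, 9), rep(NA, 0))
  calls <- cbind(g1, rep(0L, 10), g3, c(rep(NA, 8), 1L, 0L))
  gm <- toy_gm(calls)
  res <- filter_loci_by_maf(gm, 0.05)
  # locus 1 kept (0.05), locus 2 monomorphic dropped, locus 3 (0.1) kept,
  # locus 4: 1/4 copies = 0.25 kept
  expect_equal(ncol(res$gm$calls), 3L)
  expect_equal(res$report$removed, "chr1:2000")
  # 2 alt copies out of 50 observed -> 0.04 -> removed
  g_low <- cbind(c(2L, rep(0L, 24)))
  expect_equal(ncol(filter_loci_by_maf(toy_gm(g_low), 0.05)$gm$calls), 0L)
  # all-missing locus flagged
  gm_na <- toy_gm(cbind(c(1L, 1L), c(NA, NA)))
  res_na <- filter_loci_by_maf(gm_na, 0.05)
  expect_equal(res_na$report$all_missing, "chr1:2000")
})

test_that("distance thinning never keeps conflicting loci and is seeded", {
  gm <- toy_gm(matrix(0:1, 4, 3), pos = c(100, 5000, 10200))
  res <- thin_loci_by_distance(gm, 10000, seed = 3)
  kept <- res$gm$loci$pos
  expect_true(identical(sort(kept), c(100L, 10200L)) ||
                identical(kept, 5000L))
  # loci on different chromosomes never conflict
  gm2 <- toy_gm(matrix(0:1, 4, 3), chrom = c("c1", "c2", "c3"),
                pos = c(100, 120, 140))
  expect_equal(ncol(thin_loci_by_distance(gm2, 10000, seed = 1)$gm$calls), 3L)
  # determinism under the seed
  big <- toy_gm(matrix(0L, 2, 200),
                pos = sort(sample.int(3e5, 200)))
  a <- thin_loci_by_distance(big, 10000, seed = 11)$gm$loci$pos
  b <- thin_loci_by_distance(big, 10000, seed = 11)$gm$loci$pos
  expect_identical(a, b)
  # post-condition on a random instance: no within-chromosome conflicts
  expect_true(all(diff(sort(a)) >= 10000))
})

test_that("filters are idempotent", {
  set.seed(42)
  calls <- matrix(sample(c(0:2, NA), 300, replace = TRUE, prob = c(.4, .2, .2, .2)),
                  nrow = 10)
  gm <- toy_gm(calls, pos = sort(sample.int(5e5, 30)))
  f1 <- filter_individuals_by_call_rate(gm, 0.75)$gm
  expect_equal(filter_individuals_by_call_rate(f1, 0.75)$gm$calls, f1$calls)
  f2 <- filter_loci_by_maf(gm, 0.05)$gm
  expect_equal(filter_loci_by_maf(f2, 0.05)$gm$calls, f2$calls)
  f3 <- thin_loci_by_distance(gm, 10000, seed = 2)$gm
  f3b <- thin_loci_by_distance(f3, 10000, seed = 2)$gm
  expect_equal(ncol(f3b$calls), ncol(f3$calls))
})

test_that("popmap round-trip and validation", {
  pm <- tibble::tibble(sample = c("a", "b"), pop = c("X", "Y"),
                       lat = c(10, -20), lon = c(100, -150))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_popmap(pm, path)
  expect_equal(read_popmap(path), pm)
  expect_error(validate_popmap(tibble::tibble(sample = c("a", "a"),
                                              pop = c("X", "Y"))),
               "at most one")
  expect_error(validate_popmap(tibble::tibble(sample = "a", pop = "X",
                                              lat = 95, lon = 0)), "latitude")
})

test_that("HWE exact test matches hand-derived small cases", {
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3, tolerance = 1e-12)
  expect_equal(hwe_exact_test(0, 2, 0), 1, tolerance = 1e-12)
  expect_equal(hwe_exact_test(5, 0, 0), 1) # monomorphic
  expect_error(hwe_exact_test(0, 0, 0), "non-zero")
})

test_that("HWE test is calibrated under Hardy-Weinberg sampling", {
  set.seed(31)
  n_loci <- 2500
  n <- 40
  p <- runif(n_loci, 0.1, 0.9)
  pvals <- vapply(p, function(pp) {
    g <- rbinom(n, 1, pp) + rbinom(n, 1, pp)
    hwe_exact_test(sum(g == 0), sum(g == 1), sum(g == 2))
  }, numeric(1))
  for (alpha in c(0.05, 0.01)) {
    hit <- mean(pvals < alpha)
    half <- 2.58 * sqrt(alpha * (1 - alpha) / n_loci)
    # exact tests are conservative for discrete data: upper envelope only,
    # lower side bounded away from zero by the 99% binomial envelope centre
    expect_lt(hit, alpha + half)
  }
})
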