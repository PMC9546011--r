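#' Diploid biallelic genotype matrices
#'
#' The central genotype container: a samples x loci matrix of alternative
#' allele counts (0/1/2, `NA` for missing) plus a locus table carrying
#' chromosome, 1-based position, reference and alternative alleles and,
#' optionally, an ancestral allele.
#'
#' @param calls integer matrix, samples in rows, loci in columns, values in
#'   {0, 1, 2, NA}.
#' @param loci tibble with columns `chrom`, `pos`, `ref`, `alt` and
#'   optionally `anc`; one row per column of `calls`.
#' @param sample_ids character vector of sample labels (defaults to
#'   rownames of `calls`).
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(calls, loci, sample_ids = rownames(calls)) {
  calls <- as.matrix(calls)
  storage.mode(calls) <- "integer"
  loci <- as_tibble(loci)
  if (is.null(sample_ids)) sample_ids <- sprintf("S%03d", seq_len(nrow(calls)))
  stopifnot(ncol(calls) == nrow(loci), length(sample_ids) == nrow(calls))
  bad <- calls[!is.na(calls)]
  if (length(bad) && !all(bad %in% 0:2))
    stop("non-missing calls must be 0, 1 or 2")
  if (nrow(loci)) {
    if (any(loci$pos <= 0) || any(loci$pos != round(loci$pos)))
      stop("positions must be positive integers")
    if (anyDuplicated(paste(loci$chrom, loci$pos)))
      stop("(chromosome, position) pairs must be unique")
  }
  rownames(calls) <- sample_ids
  structure(list(calls = calls, loci = loci, sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("<genotype_matrix> ", nrow(x$calls), " samples x ", ncol(x$calls),
      " loci; ", format(round(100 * mean(is.na(x$calls)), 2)),
      "% missing\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$calls)

# subset helper used throughout the filters
gm_subset <- function(gm, samples = NULL, loci = NULL) {
  calls <- gm$calls
  ids <- gm$sample_ids
  tab <- gm$loci
  if (!is.null(samples)) {
    calls <- calls[samples, , drop = FALSE]
    ids <- ids[samples]
  }
  if (!is.null(loci)) {
    calls <- calls[, loci, drop = FALSE]
    tab <- tab[loci, , drop = FALSE]
  }
  genotype_matrix(calls, tab, ids)
}

#' Read a VCF into a genotype matrix
#'
#' Parses a VCF 4.x file (via \pkg{vcfR}), keeping biallelic SNPs with a GT
#' field. Multi-allelic records are skipped with a message; `./.` genotypes
#' become `NA`.
#'
#' @param path path to a `.vcf` (or `.vcf.gz`) file.
#' @return a [genotype_matrix()].
#' @export
read_vcf <- function(path) {
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e) stop("malformed VCF '", path, "': ",
                                         conditionMessage(e)))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  alt <- fix[, "ALT"]
  ref <- fix[, "REF"]
  biallelic <- !is.na(alt) & !grepl(",", alt) &
    nchar(ref) == 1 & nchar(alt) == 1
  if (sum(biallelic) == 0)
    stop("no biallelic SNPs found in '", path, "'")
  if (any(!biallelic))
    message("skipping ", sum(!biallelic), " non-biallelic-SNP record(s)")
  gt <- vcfR::extract.gt(v, element = "GT")
  gt <- gt[biallelic, , drop = FALSE]
  counts <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  clean <- gsub("\\|", "/", gt)
  counts[clean == "0/0"] <- 0L
  counts[clean %in% c("0/1", "1/0")] <- 1L
  counts[clean == "1/1"] <- 2L
  loci <- tibble(chrom = fix[biallelic, "CHROM"],
                 pos = as.integer(fix[biallelic, "POS"]),
                 ref = ref[biallelic], alt = alt[biallelic])
  genotype_matrix(t(counts), loci, sample_ids = colnames(gt))
}

#' Write a genotype matrix as VCF
#'
#' Emits an uncompressed, minimal VCF 4.2 file with GT-only genotype fields,
#' re-readable by [read_vcf()] with identical content.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @export
write_vcf <- function(gm, path) {
  con <- tryCatch(file(path, "w"),
                  error = function(e) stop("cannot write '", path, "'"))
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gm$sample_ids), collapse = "\t")),
             con)
  if (ncol(gm$calls) == 0) return(invisible(path))
  code <- c("0/0", "0/1", "1/1")
  gt <- matrix("./.", nrow = ncol(gm$calls), ncol = nrow(gm$calls))
  ok <- !is.na(t(gm$calls))
  gt[ok] <- code[t(gm$calls)[ok] + 1L]
  lines <- paste(gm$loci$chrom, gm$loci$pos, ".", gm$loci$ref, gm$loci$alt,
                 ".", "PASS", ".", "GT",
                 apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(lines, con)
  invisible(path)
}

#' Read a population map
#'
#' Two- or four-column TSV: sample, population and optionally latitude and
#' longitude in decimal degrees.
#'
#' @param path TSV path (no header required; a `sample<TAB>pop` header line
#'   is tolerated).
#' @return tibble with columns `sample`, `pop` and, when present, `lat`,
#'   `lon`.
#' @export
read_popmap <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- grepl("^sample\\b", first)
  df <- utils::read.table(path, sep = "\t", header = has_header,
                          stringsAsFactors = FALSE)
  if (ncol(df) == 2) names(df) <- c("sample", "pop")
  else if (ncol(df) == 4) names(df) <- c("sample", "pop", "lat", "lon")
  else stop("popmap must have 2 or 4 columns")
  pm <- as_tibble(df)
  validate_popmap(pm)
  pm
}

validate_popmap <- function(pm) {
  if (anyDuplicated(pm$sample))
    stop("each sample may be mapped to at most one population")
  if ("lat" %in% names(pm)) {
    if (any(pm$lat < -90 | pm$lat > 90, na.rm = TRUE))
      stop("latitudes must lie in [-90, 90]")
    if (any(pm$lon < -180 | pm$lon > 180, na.rm = TRUE))
      stop("longitudes must lie in [-180, 180]")
  }
  invisible(pm)
}

#' @rdname read_popmap
#' @param pm popmap tibble.
#' @export
write_popmap <- function(pm, path) {
  utils::write.table(pm, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

# FilterReport constructor: shared by all filters
filter_report <- function(filter, removed, threshold, seed = NA) {
  structure(list(filter = filter, removed = removed,
                 threshold = threshold, seed = seed,
                 n_removed = length(removed)),
            class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat("<filter_report> ", x$filter, ": removed ", x$n_removed,
      " item(s) at threshold ", format(x$threshold), "\n", sep = "")
  invisible(x)
}

#' Write a filter report as TSV (plus a JSON log line)
#'
#' @param report a filter report as returned by the filtering functions.
#' @param path output TSV path; a `.json` sidecar records the threshold and
#'   seed.
#' @export
write_filter_report <- function(report, path) {
  utils::write.table(
    data.frame(filter = report$filter,
               removed = if (length(report$removed)) report$removed else NA),
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(filter = report$filter, threshold = report$threshold,
         seed = report$seed, n_removed = report$n_removed),
    paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}
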