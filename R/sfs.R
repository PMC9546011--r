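#' Joint site-frequency spectra
#'
#' A `joint_sfs` holds a one- or two-population derived-allele-count
#' spectrum: a real-valued array of per-cell site counts indexed by derived
#' allele count 0..n per population, a logical mask of excluded cells (at
#' minimum the all-ancestral and all-derived corners), the gene-copy sample
#' sizes and population labels, and a polarization flag.
#'
#' @param counts numeric vector (1 population) or matrix (2 populations)
#'   with dimension `n1 + 1` (`x (n2 + 1)`).
#' @param sizes gene-copy sample sizes, length 1 or 2.
#' @param pops population labels.
#' @param polarized `TRUE` when cells index derived (not minor) allele
#'   counts.
#' @param mask optional logical array of the same shape, `TRUE` = excluded;
#'   the corners are always masked in addition.
#' @export
joint_sfs <- function(counts, sizes, pops = NULL, polarized = TRUE,
                      mask = NULL) {
  counts <- if (length(sizes) == 1) {
    matrix(as.numeric(counts), ncol = 1)
  } else {
    as.matrix(counts)
  }
  sizes <- as.integer(sizes)
  expected <- c(sizes[1] + 1L, if (length(sizes) == 2) sizes[2] + 1L else 1L)
  if (!all(dim(counts) == expected))
    stop("counts shape ", paste(dim(counts), collapse = "x"),
         " does not match sizes (", paste(sizes, collapse = ", "), ")")
  if (any(counts < 0)) stop("spectrum counts must be >= 0")
  if (is.null(pops)) pops <- paste0("pop", seq_along(sizes))
  m <- matrix(FALSE, nrow(counts), ncol(counts))
  if (!is.null(mask)) m <- m | mask
  m[1, 1] <- TRUE                      # all-ancestral corner
  m[nrow(m), ncol(m)] <- TRUE          # all-derived corner
  structure(list(counts = counts, sizes = sizes, pops = pops,
                 polarized = polarized, mask = m),
            class = "joint_sfs")
}

#' @export
print.joint_sfs <- function(x, ...) {
  cat("<joint_sfs> ", length(x$sizes), "-population, sizes (",
      paste(x$sizes, collapse = ", "), "), ",
      if (x$polarized) "polarized" else "folded/unpolarized",
      "; ", format(round(sum(x$counts[!x$mask]), 2)),
      " sites in unmasked cells\n", sep = "")
  invisible(x)
}

sfs_total <- function(sfs) sum(sfs$counts[!sfs$mask])

#' Build a polarized joint SFS from genotypes
#'
#' Polarizes each locus against an outgroup allele table: where the outgroup
#' base matches exactly one of the two alleles that allele is taken as
#' ancestral, and the locus increments the spectrum cell indexed by the
#' derived allele count in each focal population. Loci with any missing call
#' in the focal samples, absent from the outgroup table, or whose outgroup
#' base matches neither allele are dropped and tallied in the attached
#' report.
#'
#' @param gm a [genotype_matrix()].
#' @param popmap popmap tibble (`sample`, `pop`).
#' @param pops one or two population labels.
#' @param outgroup tibble `chrom`, `pos`, `allele` of outgroup bases.
#' @return a [joint_sfs()] with a `drop_report` attribute.
#' @export
build_joint_sfs <- function(gm, popmap, pops, outgroup) {
  stopifnot(length(pops) %in% 1:2)
  missing_pops <- setdiff(pops, popmap$pop)
  if (length(missing_pops))
    stop("population(s) absent from popmap: ",
         paste(missing_pops, collapse = ", "))
  if (anyDuplicated(paste(outgroup$chrom, outgroup$pos)))
    stop("outgroup positions must be unique")
  samples <- lapply(pops, function(p)
    match(popmap$sample[popmap$pop == p], gm$sample_ids))
  if (any(is.na(unlist(samples))))
    stop("popmap refers to samples absent from the genotype matrix")
  sizes <- vapply(samples, function(s) 2L * length(s), integer(1))

  key <- paste(gm$loci$chrom, gm$loci$pos)
  og <- outgroup$allele[match(key, paste(outgroup$chrom, outgroup$pos))]
  anc_is_ref <- !is.na(og) & og == gm$loci$ref
  anc_is_alt <- !is.na(og) & og == gm$loci$alt
  usable_og <- xor(anc_is_ref, anc_is_alt)

  focal <- unlist(samples)
  complete <- colSums(is.na(gm$calls[focal, , drop = FALSE])) == 0
  keep <- usable_og & complete

  counts <- array(0, dim = c(sizes[1] + 1L,
                             if (length(sizes) == 2) sizes[2] + 1L else 1L))
  if (any(keep)) {
    idx <- lapply(seq_along(pops), function(k) {
      alt_count <- colSums(gm$calls[samples[[k]], keep, drop = FALSE])
      # derived = alt where ancestral is ref, else flipped
      ifelse(anc_is_ref[keep], alt_count, sizes[k] - alt_count)
    })
    if (length(pops) == 1) {
      tab <- tabulate(idx[[1]] + 1L, nbins = sizes[1] + 1L)
      counts[, 1] <- tab
    } else {
      for (i in seq_len(sum(keep)))
        counts[idx[[1]][i] + 1L, idx[[2]][i] + 1L] <-
          counts[idx[[1]][i] + 1L, idx[[2]][i] + 1L] + 1
    }
  }
  out <- joint_sfs(counts, sizes, pops = pops, polarized = TRUE)
  attr(out, "drop_report") <- tibble(
    reason = c("outgroup_uninformative", "missing_calls", "used"),
    n = c(sum(!usable_og), sum(usable_og & !complete), sum(keep)))
  out
}

# hypergeometric projection matrix: W[i+1, j+1] = P(j of m | i of n)
projection_matrix <- function(n, m) {
  outer(0:n, 0:m, function(i, j) dhyper(j, i, n - i, m))
}

#' Project a spectrum to smaller sample sizes
#'
#' Expectation-preserving hypergeometric downsampling: each source cell
#' redistributes its count over target cells with weights
#' `choose(i, j) choose(n - i, m - j) / choose(n, m)`. Total mass (including
#' mass moved into the re-masked corners) is conserved.
#'
#' @param sfs a [joint_sfs()].
#' @param target_sizes gene-copy sizes, one per population, each between 2
#'   and the current size.
#' @export
project <- function(sfs, target_sizes) {
  target_sizes <- as.integer(target_sizes)
  stopifnot(length(target_sizes) == length(sfs$sizes))
  if (any(target_sizes > sfs$sizes))
    stop("target sizes must not exceed current sizes")
  if (any(target_sizes < 2)) stop("target sizes must be >= 2")
  counts <- sfs$counts
  w1 <- projection_matrix(sfs$sizes[1], target_sizes[1])
  out <- t(w1) %*% counts
  if (length(sfs$sizes) == 2) {
    w2 <- projection_matrix(sfs$sizes[2], target_sizes[2])
    out <- out %*% w2
  }
  joint_sfs(out, target_sizes, pops = sfs$pops, polarized = sfs$polarized)
}

#' Fold a spectrum onto minor-allele counts
#'
#' Sums each cell with its complement, leaving the minor-allele half of the
#' array; the redundant half is zeroed and masked. Folding is idempotent.
#'
#' @param sfs a [joint_sfs()].
#' @export
fold <- function(sfs) {
  cnt <- sfs$counts
  d <- dim(cnt)
  n_tot <- sum(sfs$sizes)
  ii <- outer(0:(d[1] - 1), 0:(d[2] - 1), function(i, j) i + j)
  folded <- cnt * 0
  for (a in seq_len(d[1])) {
    for (b in seq_len(d[2])) {
      ca <- d[1] - a + 1
      cb <- d[2] - b + 1
      tot <- ii[a, b]
      if (2 * tot < n_tot) {
        folded[a, b] <- cnt[a, b] + cnt[ca, cb]
      } else if (2 * tot == n_tot) {
        folded[a, b] <- if (a < ca || (a == ca && b <= cb))
          cnt[a, b] + (if (a == ca && b == cb) 0 else cnt[ca, cb]) else 0
      }
    }
  }
  mask <- ii * 2 > n_tot | (ii * 2 == n_tot &
    outer(seq_len(d[1]), seq_len(d[2]), function(a, b) {
      ca <- d[1] - a + 1; cb <- d[2] - b + 1
      a > ca | (a == ca & b > cb)
    }))
  joint_sfs(folded, sfs$sizes, pops = sfs$pops, polarized = FALSE,
            mask = mask)
}

#' Marginalize a two-population spectrum
#'
#' Sums over the other population's axis, yielding the one-population
#' spectrum with corner masking re-applied.
#'
#' @param sfs a two-population [joint_sfs()].
#' @param pop label (or index) of the population to keep.
#' @export
marginalize <- function(sfs, pop) {
  if (length(sfs$sizes) != 2) stop("marginalize requires a 2-population SFS")
  k <- if (is.character(pop)) match(pop, sfs$pops) else as.integer(pop)
  if (is.na(k) || !k %in% 1:2) stop("unknown population: ", pop)
  cnt <- if (k == 1) rowSums(sfs$counts) else colSums(sfs$counts)
  joint_sfs(cnt, sfs$sizes[k], pops = sfs$pops[k], polarized = sfs$polarized)
}

#' Read and write spectra in the dadi text format
#'
#' The header line carries the array shape, an `unfolded`/`folded` flag and
#' optional quoted population labels; the second line the whitespace
#' separated cell counts; the third the mask row (1 = masked).
#'
#' @param path file path.
#' @return a [joint_sfs()].
#' @export
read_dadi_sfs <- function(path) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*#", lines) & nzchar(trimws(lines))]
  hdr <- strsplit(trimws(lines[1]), "\\s+")[[1]]
  shape <- suppressWarnings(as.integer(hdr))
  shape <- shape[!is.na(shape)]
  folded <- any(hdr == "folded")
  pops <- gsub('"', "", hdr[grepl('^"', hdr)])
  vals <- as.numeric(strsplit(trimws(lines[2]), "\\s+")[[1]])
  if (length(vals) != prod(shape))
    stop("data length ", length(vals), " does not match header shape ",
         paste(shape, collapse = "x"))
  mask <- rep(FALSE, prod(shape))
  if (length(lines) >= 3) {
    mv <- as.integer(strsplit(trimws(lines[3]), "\\s+")[[1]])
    if (length(mv) != prod(shape)) stop("mask length does not match shape")
    mask <- mv == 1L
  }
  # dadi arrays are row-major (C order): last index varies fastest
  if (length(shape) == 2) {
    cnt <- matrix(vals, nrow = shape[1], ncol = shape[2], byrow = TRUE)
    msk <- matrix(mask, nrow = shape[1], ncol = shape[2], byrow = TRUE)
  } else {
    cnt <- vals
    msk <- matrix(mask, ncol = 1)
  }
  joint_sfs(cnt, shape - 1L,
            pops = if (length(pops)) pops else NULL,
            polarized = !folded, mask = msk)
}

#' @rdname read_dadi_sfs
#' @param sfs a [joint_sfs()].
#' @export
write_dadi_sfs <- function(sfs, path) {
  shape <- dim(sfs$counts)
  if (length(sfs$sizes) == 1) shape <- shape[1]
  hdr <- paste(c(shape, if (sfs$polarized) "unfolded" else "folded",
                 paste0('"', sfs$pops, '"')), collapse = " ")
  vals <- if (length(shape) == 2) as.vector(t(sfs$counts)) else sfs$counts[, 1]
  msk <- if (length(shape) == 2) as.vector(t(sfs$mask)) else sfs$mask[, 1]
  writeLines(c(hdr,
               paste(format(vals, digits = 15, trim = TRUE, scientific = FALSE),
                     collapse = " "),
               paste(as.integer(msk), collapse = " ")), path)
  invisible(path)
}
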