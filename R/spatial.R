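#' Pairwise genetic and geographic distance matrices
#'
#' Labelled symmetric matrices with zero diagonal and a kind tag
#' (`edwards`, `ibs` or `geographic_km`). Pairs with no shared genotyped
#' loci (or missing coordinates) get `NA` and are listed in the
#' `missing_pairs` attribute.
#'
#' @name distances
NULL

dist_matrix <- function(m, labels, kind) {
  dimnames(m) <- list(labels, labels)
  diag(m) <- 0
  structure(m, kind = kind, class = c("dist_matrix", "matrix", "array"))
}

#' @export
print.dist_matrix <- function(x, ...) {
  cat("<dist_matrix> kind:", attr(x, "kind"), "-", nrow(x), "items\n")
  print(unclass(x)[seq_len(min(6, nrow(x))), seq_len(min(6, ncol(x)))])
  invisible(x)
}

# shared pairwise loop over individual "allele frequency" encodings
pairwise_genetic <- function(gm, pair_fun, kind) {
  g <- gm$calls
  ns <- nrow(g)
  if (ns < 2) stop("need >= 2 samples")
  m <- matrix(NA_real_, ns, ns)
  missing_pairs <- list()
  for (x in seq_len(ns - 1)) {
    for (y in seq((x + 1), ns)) {
      shared <- !is.na(g[x, ]) & !is.na(g[y, ])
      if (!any(shared)) {
        missing_pairs[[length(missing_pairs) + 1]] <-
          c(gm$sample_ids[x], gm$sample_ids[y])
        next
      }
      m[x, y] <- m[y, x] <- pair_fun(g[x, shared], g[y, shared])
    }
  }
  out <- dist_matrix(m, gm$sample_ids, kind)
  attr(out, "missing_pairs") <- missing_pairs
  out
}

#' Edwards' angular genetic distance between individuals
#'
#' Individuals are treated as two-allele "populations" with allele
#' frequencies 0, 1/2 or 1 from their genotype, and the pairwise angular
#' distance over the L loci genotyped in both is
#' `D = sqrt(1 - (1/L) sum_l sum_alleles sqrt(p_x p_y))`, bounded in
#' \[0, 1\].
#'
#' @param gm a [genotype_matrix()].
#' @return a `dist_matrix` of kind `edwards`.
#' @export
edwards_distance <- function(gm) {
  pairwise_genetic(gm, function(a, b) {
    pa <- a / 2
    pb <- b / 2
    cosang <- mean(sqrt(pa * pb) + sqrt((1 - pa) * (1 - pb)))
    sqrt(max(0, 1 - cosang))
  }, "edwards")
}

#' Identity-by-state distance between individuals
#'
#' Mean over shared loci of `|g_x - g_y| / 2`.
#'
#' @inheritParams edwards_distance
#' @export
ibs_distance <- function(gm) {
  pairwise_genetic(gm, function(a, b) mean(abs(a - b) / 2), "ibs")
}

#' Great-circle distances from coordinates
#'
#' Haversine distance with Earth radius 6371.0 km.
#'
#' @param coords tibble with columns `sample` (or `deme`), `lat`, `lon` in
#'   decimal degrees.
#' @return a `dist_matrix` of kind `geographic_km`.
#' @export
geographic_distance <- function(coords) {
  coords <- as_tibble(coords)
  label_col <- intersect(c("sample", "deme"), names(coords))[1]
  labels <- coords[[label_col]]
  n <- nrow(coords)
  m <- matrix(NA_real_, n, n)
  ok <- !is.na(coords$lat) & !is.na(coords$lon)
  pts <- cbind(coords$lon, coords$lat)
  for (x in seq_len(n)) {
    if (!ok[x]) next
    d <- geosphere::distHaversine(pts[x, ], pts[ok, , drop = FALSE],
                                  r = 6371000)
    m[x, ok] <- d / 1000
  }
  out <- dist_matrix(m, labels, "geographic_km")
  attr(out, "missing_pairs") <- labels[!ok]
  out
}

#' Mantel test of matrix association
#'
#' Pearson correlation of the corresponding off-diagonal entries of two
#' labelled distance matrices, with a one-sided (greater) permutation null
#' built by jointly permuting rows and columns of the second matrix:
#' `p = (1 + #\{r_perm >= r_obs\}) / (1 + n_perm)`. This is the standard
#' isolation-by-distance test of genetic against geographic distances.
#'
#' @param genetic,geographic `dist_matrix` objects with identical label
#'   sets.
#' @param n_perm number of permutations.
#' @param seed RNG seed.
#' @return tibble `r`, `p`, `n_perm`, `seed`.
#' @export
mantel_test <- function(genetic, geographic, n_perm = 999, seed = 1) {
  if (n_perm < 1) stop("n_perm must be >= 1")
  if (!setequal(rownames(genetic), rownames(geographic)))
    stop("label sets of the two matrices do not match")
  geo <- geographic[rownames(genetic), rownames(genetic)]
  n <- nrow(genetic)
  lower <- lower.tri(genetic)
  gvec <- genetic[lower]
  r_obs <- cor(gvec, geo[lower], use = "complete.obs")
  r_perm <- withr::with_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      p <- sample.int(n)
      cor(gvec, geo[p, p][lower], use = "complete.obs")
    }, numeric(1))
  })
  tibble(r = r_obs, p = (1 + sum(r_perm >= r_obs)) / (1 + n_perm),
         n_perm = n_perm, seed = seed)
}

#' Neighbour-joining tree from a distance matrix
#'
#' Standard Saitou-Nei agglomeration (via \pkg{ape}). Negative branch
#' lengths, which NJ can produce on non-additive inputs, are clamped to
#' zero with the `clamped` attribute set.
#'
#' @param d a `dist_matrix` (or plain labelled symmetric matrix) with at
#'   least 3 items.
#' @return an unrooted `phylo` tree.
#' @export
neighbor_joining <- function(d) {
  if (nrow(d) < 3) stop("neighbour joining needs >= 3 items")
  tree <- ape::nj(stats::as.dist(unclass(d)))
  clamped <- any(tree$edge.length < 0)
  if (clamped) {
    warning("negative NJ branch lengths clamped to 0")
    tree$edge.length[tree$edge.length < 0] <- 0
  }
  attr(tree, "clamped") <- clamped
  tree
}

#' @rdname neighbor_joining
#' @param tree a `phylo` tree.
#' @param path output newick path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
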