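#' Venn partition of 2-5 gene sets
#'
#' Exact region counts by set algebra: each element of the union is
#' assigned to the unique region given by its membership pattern; the 2^n
#' - 1 region counts therefore sum to the union size and the regions are
#' disjoint by construction.
#'
#' @param sets named list of 2-5 character vectors
#' @return named integer vector over the 2^n - 1 non-empty membership
#'   patterns; names join member set labels with `&`
#' @export
vennPartition <- function(sets) {
  n <- length(sets)
  if (n < 2L || n > 5L) stop("vennPartition supports 2 to 5 sets")
  if (is.null(names(sets)) || any(names(sets) == ""))
    stop("sets must be named")
  sets <- lapply(sets, unique)
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  member <- matrix(member, ncol = n)
  patterns <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1L, , drop = FALSE]
  counts <- apply(patterns, 1L, function(p)
    sum(colSums(t(member) == p) == n))
  names(counts) <- apply(patterns, 1L, function(p)
    paste(names(sets)[as.logical(p)], collapse = "&"))
  counts
}

#' Reconstruct the original sets from a Venn partition's regions
#'
#' Utility used to check region/set consistency: the size of set `label`
#' equals the sum of counts over all regions containing `label`.
#'
#' @param partition output of [vennPartition()]
#' @param label set label
#' @return integer implied set size
#' @export
vennSetSize <- function(partition, label) {
  hit <- vapply(strsplit(names(partition), "&", fixed = TRUE),
                function(v) label %in% v, logical(1))
  sum(partition[hit])
}

#' Hypergeometric (one-sided Fisher) overlap significance
#'
#' Significance of the overlap between two gene sets drawn from a common
#' universe: `p = P[X >= k]` for `X ~ Hypergeometric(n_universe, n_a,
#' n_b)`, identical to the one-sided Fisher exact test of the 2x2 table.
#' One-sided because the question is over-representation of shared genes.
#'
#' @param n_a,n_b set sizes
#' @param k observed overlap
#' @param n_universe background size (default 22089, the gene count of the
#'   CATMA v5 Arabidopsis array)
#' @return list: `n_a`, `n_b`, `k`, `n_universe`, `expected`, `p_value`
#' @export
overlapPvalue <- function(n_a, n_b, k, n_universe = 22089L) {
  if (n_a > n_universe || n_b > n_universe)
    stop("set sizes exceed the universe")
  if (k > min(n_a, n_b) || k < max(0L, n_a + n_b - n_universe))
    stop("overlap k outside its feasible bounds")
  p <- phyper(k - 1L, n_a, n_universe - n_a, n_b, lower.tail = FALSE)
  list(n_a = n_a, n_b = n_b, k = k, n_universe = n_universe,
       expected = n_a * n_b / n_universe, p_value = p)
}

#' Core set shared with external gene lists
#'
#' Intersects a reference DEG list with the union of external study lists
#' and reports the shared fraction as a percentage.
#'
#' @param reference character vector of reference gene ids (nonempty)
#' @param external_lists named list of external gene id vectors
#' @param decimals decimal places for the formatted percentage
#' @return list: `shared` (character), `n_shared`, `n_reference`,
#'   `fraction` (numeric percent), `label` (e.g. `"77.7 %"`)
#' @export
coreSet <- function(reference, external_lists, decimals = 1) {
  reference <- unique(reference)
  if (!length(reference)) stop("reference set must be nonempty")
  pool <- unique(unlist(external_lists))
  shared <- intersect(reference, pool)
  frac <- if (length(pool)) 100 * length(shared) / length(reference) else 0
  list(shared = shared, n_shared = length(shared),
       n_reference = length(reference), fraction = frac,
       label = paste(formatPercent(frac, decimals), "%"))
}

#' Format a percentage with half-away-from-zero rounding
#'
#' `round()` rounds half to even; reported percentages round halves away
#' from zero (62.5 -> 63, -62.5 -> -63).
#'
#' @param x numeric percent value
#' @param decimals decimal places
#' @return character
#' @export
formatPercent <- function(x, decimals = 0) {
  m <- 10^decimals
  v <- sign(x) * floor(abs(x) * m + 0.5) / m
  formatC(v, format = "f", digits = decimals)
}

#' Hierarchical clustering of expression profiles
#'
#' Agglomerative clustering of gene profiles by Euclidean distance with
#' average linkage (pluggable). `stats::hclust` breaks ties
#' deterministically by input order, so row permutations give the same
#' tree topology up to leaf order.
#'
#' @param profiles numeric matrix genes x conditions, no missing values
#' @param linkage linkage method passed to [stats::hclust()]
#' @return an `hclust` tree; serialize with [writeNewick()]
#' @export
profileHclust <- function(profiles, linkage = "average") {
  profiles <- as.matrix(profiles)
  if (nrow(profiles) < 2L) stop("need >= 2 profiles")
  if (anyNA(profiles)) stop("missing values: impute or filter first")
  hclust(dist(profiles, method = "euclidean"), method = linkage)
}

#' Serialize a dendrogram as Newick
#'
#' Branch lengths derive from the merge heights (via
#' [ape::as.phylo.hclust]).
#'
#' @param tree an `hclust` object
#' @param path output file path
#' @return the path, invisibly
#' @export
writeNewick <- function(tree, path) {
  phy <- ape::as.phylo(tree)
  ape::write.tree(phy, file = path)
  invisible(path)
}
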