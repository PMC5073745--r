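#' Functional-bin over/under-representation of a gene set
#'
#' MapMan-bin-style enrichment: for each bin, the normalized frequency
#' `(n_in_set / n_set) / (n_in_universe / n_universe)` and hypergeometric
#' tail p-values (over-representation `P[X >= n_in_set]`,
#' under-representation `P[X <= n_in_set]`). Genes may carry several bins
#' and count once per bin. No multiplicity correction is applied by
#' default (raw p-values at `alpha`), matching the SuperViewer-style
#' report; set `correct = "BH"` to adjust.
#'
#' Genes in `gene_set` absent from the annotation universe are dropped
#' with a warning.
#'
#' @param gene_set character vector of gene ids
#' @param annotation data.frame (`gene_id`, `bin`), one row per
#'   gene-bin assignment
#' @param universe character vector of background gene ids; defaults to
#'   all annotated genes
#' @param alpha significance level for the `significant` flag
#' @param correct `"none"` (default) or `"BH"`
#' @return data.frame, one row per bin: counts, `normalized_frequency`,
#'   `p_over`, `p_under`, `direction` (`"over"`/`"under"`), `p_value`
#'   (tail matching `direction`), `significant`
#' @export
binEnrichment <- function(gene_set, annotation,
                          universe = unique(annotation$gene_id),
                          alpha = 0.05, correct = c("none", "BH")) {
  correct <- match.arg(correct)
  gene_set <- unique(gene_set)
  if (!length(gene_set)) stop("gene_set must be nonempty")
  annotation <- annotation[annotation$gene_id %in% universe, , drop = FALSE]
  lost <- setdiff(gene_set, universe)
  if (length(lost)) {
    warning(length(lost), " gene(s) outside the universe dropped")
    gene_set <- setdiff(gene_set, lost)
    if (!length(gene_set)) stop("no gene_set members in the universe")
  }
  nU <- length(universe)
  nS <- length(gene_set)
  bins <- sort(unique(annotation$bin))
  rows <- lapply(bins, function(b) {
    members <- unique(annotation$gene_id[annotation$bin == b])
    K <- length(members)
    k <- length(intersect(members, gene_set))
    nf <- (k / nS) / (K / nU)
    pOver <- phyper(k - 1L, K, nU - K, nS, lower.tail = FALSE)
    pUnder <- phyper(k, K, nU - K, nS)
    dir <- if (nf >= 1) "over" else "under"
    data.frame(bin = b, n_in_set = k, n_set = nS, n_in_universe = K,
               n_universe = nU, normalized_frequency = nf,
               p_over = pOver, p_under = pUnder, direction = dir,
               p_value = if (dir == "over") pOver else pUnder,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (correct == "BH") out$p_value <- bhAdjust(out$p_value)
  out$significant <- out$p_value < alpha
  out[order(out$p_value, out$bin), , drop = FALSE]
}

#' Enrichment across timepoints and directions
#'
#' Runs [binEnrichment()] separately on the up- and downregulated gene
#' set of each timepoint's `DEGSet` and stacks the results in long
#' format. Empty sets are skipped with a message.
#'
#' @param deg_sets named list of `DEGSet` (from [degTimecourse()])
#' @param annotation,universe,alpha,correct see [binEnrichment()]
#' @return long-format data.frame: `timepoint`, `direction`, then the
#'   [binEnrichment()] columns
#' @export
enrichmentTimecourse <- function(deg_sets, annotation,
                                 universe = unique(annotation$gene_id),
                                 alpha = 0.05, correct = c("none", "BH")) {
  correct <- match.arg(correct)
  out <- list()
  for (tp in names(deg_sets)) {
    for (dir in c("up", "down")) {
      gs <- deg_sets[[tp]][[dir]]
      gs <- intersect(gs, universe)
      if (!length(gs)) {
        message("no ", dir, "regulated genes at ", tp, " h: omitted")
        next
      }
      e <- binEnrichment(gs, annotation, universe = universe,
                         alpha = alpha, correct = correct)
      out[[length(out) + 1L]] <-
        cbind(data.frame(timepoint = tp, direction = dir,
                         stringsAsFactors = FALSE), e)
    }
  }
  if (!length(out))
    return(data.frame(timepoint = character(0), direction = character(0)))
  do.call(rbind, out)
}

#' Read a gene-to-bin annotation table
#'
#' Two-column tab-delimited file (`gene_id`, `bin`), repeated rows for
#' multi-bin genes.
#'
#' @param path file path
#' @return data.frame (`gene_id`, `bin`)
#' @export
readAnnotation <- function(path) {
  ann <- read.delim(path, stringsAsFactors = FALSE,
                    colClasses = c("character", "character"))
  if (!all(c("gene_id", "bin") %in% names(ann)))
    stop("annotation file must have columns gene_id and bin")
  ann
}
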