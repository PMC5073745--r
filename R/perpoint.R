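#' Per-comparison replicate log-ratios
#'
#' For one dye-swapped comparison, subtract the `cell_b` observation from
#' the `cell_a` observation within each of its two arrays, per gene. For
#' treated-vs-control comparisons the orientation is fixed to treated
#' minus control (positive = higher under treatment), regardless of how
#' the comparison row stores its cells; the model contains no dye term,
#' so dye-swapped replicates of a noiseless gene agree exactly.
#'
#' @param ke a [KineticExperiment-class]
#' @param comparison one-row data.frame as in `comparisons(design)`
#' @return numeric matrix genes x replicate arrays of log2 ratios
#' @export
comparisonLogRatios <- function(ke, comparison) {
  design <- kineticDesign(ke)
  obs <- observations(design)
  Y <- expressionValues(ke)
  a <- c(comparison$time_a, comparison$treatment_a)
  b <- c(comparison$time_b, comparison$treatment_b)
  # orient treated-vs-control when the comparison crosses treatments
  if (a[2L] == "control" && b[2L] == "PHN") { tmp <- a; a <- b; b <- tmp }
  arrays <- c(comparison$array_1, comparison$array_2)
  arrays <- arrays[!is.na(arrays)]
  ratios <- sapply(arrays, function(arr) {
    oa <- obs$obs_id[obs$array_id == arr & obs$time_h == as.numeric(a[1L]) &
                       obs$treatment == a[2L]]
    ob <- obs$obs_id[obs$array_id == arr & obs$time_h == as.numeric(b[1L]) &
                       obs$treatment == b[2L]]
    if (length(oa) != 1L || length(ob) != 1L)
      stop("comparison not present in the design (array ", arr, ")")
    Y[, oa] - Y[, ob]
  })
  ratios <- matrix(ratios, nrow = nrow(Y),
                   dimnames = list(rownames(Y), paste0("array", arrays)))
  ratios
}

#' Per-timepoint differential expression under familywise control
#'
#' One-sample t test of each gene's replicate log-ratios against zero,
#' with Bonferroni control: a gene is declared differentially expressed
#' iff its raw p-value is below `alpha / n_genes_tested`. Direction is the
#' sign of the mean ratio. Zero-variance genes: mean zero is not DE; a
#' nonzero mean with zero variance is flagged degenerate and called DE in
#' its mean's direction (an exact replicate agreement carries no internal
#' error estimate). With two replicates the test has one degree of
#' freedom; `pooled_variance = TRUE` instead uses a common variance
#' estimate across genes (pooled residual df), off by default.
#'
#' @param ratios genes x replicates matrix from [comparisonLogRatios()]
#' @param alpha familywise error level (default 0.05)
#' @param timepoint label stored on the result
#' @param pooled_variance use a common across-gene variance estimate
#' @return a `DEGSet` list: `timepoint`, `up`, `down` (gene id vectors),
#'   and `table` (gene_id, log2_ratio, p, p_bonferroni, direction,
#'   degenerate)
#' @export
timepointTest <- function(ratios, alpha = 0.05, timepoint = NA,
                          pooled_variance = FALSE) {
  if (alpha <= 0 || alpha > 1) stop("alpha must be in (0, 1]")
  n <- ncol(ratios)
  if (n < 2L) stop("need >= 2 replicate ratios per gene")
  m <- rowMeans(ratios)
  s <- apply(ratios, 1L, sd)
  nGenes <- nrow(ratios)
  if (pooled_variance) {
    sPool <- sqrt(mean(s^2))
    tt <- m / (sPool / sqrt(n))
    dfT <- nGenes * (n - 1L)
    p <- 2 * pt(-abs(tt), df = dfT)
    degenerate <- rep(FALSE, nGenes)
  } else {
    tt <- m / (s / sqrt(n))
    p <- 2 * pt(-abs(tt), df = n - 1L)
    zeroVar <- s == 0
    degenerate <- zeroVar & m != 0
    p[zeroVar & m == 0] <- 1
    p[degenerate] <- 0
  }
  cut <- alpha / nGenes
  de <- p < cut
  direction <- ifelse(m > 0, "up", ifelse(m < 0, "down", "none"))
  tab <- data.frame(gene_id = rownames(ratios), log2_ratio = unname(m),
                    p = unname(p), p_bonferroni = unname(pmin(p * nGenes, 1)),
                    significant = unname(de),
                    direction = unname(direction),
                    degenerate = unname(degenerate),
                    stringsAsFactors = FALSE)
  structure(list(timepoint = timepoint,
                 up = tab$gene_id[de & direction == "up"],
                 down = tab$gene_id[de & direction == "down"],
                 alpha = alpha, table = tab),
            class = "DEGSet")
}

#' @export
print.DEGSet <- function(x, ...) {
  cat("DEGSet", if (!is.na(x$timepoint)) paste0("(", x$timepoint, " h)"),
      ":", length(x$up), "up,", length(x$down),
      "down of", nrow(x$table), "genes tested (familywise alpha =",
      x$alpha, ")\n")
  invisible(x)
}

#' Per-timepoint DEG sets across the whole kinetic
#'
#' Runs [comparisonLogRatios()] + [timepointTest()] on every
#' treated-vs-control comparison of the design, in time order.
#'
#' @param ke a [KineticExperiment-class]
#' @param alpha familywise error level per timepoint
#' @param pooled_variance see [timepointTest()]
#' @return named list of `DEGSet`, names are timepoints in hours
#' @export
degTimecourse <- function(ke, alpha = 0.05, pooled_variance = FALSE) {
  cmp <- comparisons(kineticDesign(ke))
  tvc <- cmp[cmp$time_a == cmp$time_b & cmp$treatment_a != cmp$treatment_b, ,
             drop = FALSE]
  tvc <- tvc[order(tvc$time_a), , drop = FALSE]
  out <- lapply(seq_len(nrow(tvc)), function(i) {
    r <- comparisonLogRatios(ke, tvc[i, , drop = FALSE])
    r <- r[!apply(is.na(r), 1L, any), , drop = FALSE]
    timepointTest(r, alpha = alpha, timepoint = tvc$time_a[i],
                  pooled_variance = pooled_variance)
  })
  names(out) <- as.character(tvc$time_a)
  out
}
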