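#' Fit both per-gene linear models to one gene
#'
#' Ordinary least squares fits of the additive (`mu + alpha_t + beta_p +
#' delta_a`) and interaction (`... + gamma_tp`) models to one gene's
#' expression vector. Solved by QR with a relative rank tolerance of
#' 1e-10; the indicator matrices are already full-rank by construction so
#' the tolerance only guards against numerically degenerate inputs.
#'
#' @param y numeric vector, one value per design observation, no NA
#' @param design a [KineticDesign-class]
#' @return a `GeneFit` list: `rss_additive`, `rss_interaction`,
#'   `df_additive`, `df_interaction`, `coef_additive`, `coef_interaction`
#' @export
fitGene <- function(y, design) {
  obs <- observations(design)
  if (length(y) != nrow(obs))
    stop("y must have one value per design observation")
  if (anyNA(y))
    stop("missing values: gene must be skipped (all observations required)")
  fitOne <- function(variant) {
    X <- designMatrix(design, variant)
    qx <- qr(X, tol = 1e-10)
    cf <- qr.coef(qx, y)
    r <- qr.resid(qx, y)
    list(coef = cf, rss = sum(r^2), df = length(y) - qx$rank)
  }
  fa <- fitOne("additive")
  fi <- fitOne("interaction")
  structure(list(rss_additive = fa$rss, rss_interaction = fi$rss,
                 df_additive = fa$df, df_interaction = fi$df,
                 coef_additive = fa$coef, coef_interaction = fi$coef),
            class = "GeneFit")
}

#' Nested F-test for a time-by-treatment interaction
#'
#' Tests the additive model against the interaction alternative:
#' `F = ((RSS_add - RSS_int) / (df_add - df_int)) / (RSS_int / df_int)`,
#' with the p-value from the upper tail of the F distribution (on the
#' default design: F(4, 18)). Degenerate genes where both models
#' interpolate the data exactly (both RSS ~ 0) carry no evidence for an
#' interaction and get p = 1; an exact interaction fit with additive
#' lack-of-fit gets p = 0 and is flagged `degenerate`.
#'
#' @param fit a `GeneFit` from [fitGene()]
#' @param tol relative tolerance for declaring an RSS zero
#' @return list: `f_stat`, `p_value`, `df1`, `df2`, `degenerate`
#' @export
interactionTest <- function(fit, tol = 1e-10) {
  stopifnot(inherits(fit, "GeneFit"))
  if (!(fit$df_additive > fit$df_interaction && fit$df_interaction > 0))
    stop("need df_additive > df_interaction > 0")
  df1 <- fit$df_additive - fit$df_interaction
  df2 <- fit$df_interaction
  scale <- max(fit$rss_additive, 1)
  if (fit$rss_interaction <= tol * scale) {
    if (fit$rss_additive <= tol * scale)
      return(list(f_stat = 0, p_value = 1, df1 = df1, df2 = df2,
                  degenerate = TRUE))
    return(list(f_stat = Inf, p_value = 0, df1 = df1, df2 = df2,
                degenerate = TRUE))
  }
  f <- ((fit$rss_additive - fit$rss_interaction) / df1) /
       (fit$rss_interaction / df2)
  list(f_stat = f, p_value = pf(f, df1, df2, lower.tail = FALSE),
       df1 = df1, df2 = df2, degenerate = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Step-up FDR adjustment: sort p-values ascending, multiply the i-th by
#' n/i, enforce monotonicity by a cumulative minimum from the largest, cap
#' at 1, and return in input order. Delegates to
#' [stats::p.adjust()] with `method = "BH"` after validating the input.
#'
#' @param p numeric vector of p-values in `[0, 1]`
#' @return adjusted p-values, same order as input
#' @export
bhAdjust <- function(p) {
  if (anyNA(p) || any(p < 0 | p > 1))
    stop("p-values must be in [0, 1] with no missing values")
  p.adjust(p, method = "BH")
}

#' Fit both models and the interaction test across all genes
#'
#' Vectorised OLS across the gene matrix: the two model matrices are
#' QR-factorised once and residuals computed for all genes in one pass.
#' Genes with missing values are excluded from fitting and reported in
#' the `skipped` attribute ("all observations required"), matching the
#' analysis rule that only complete genes enter the models.
#'
#' @param ke a [KineticExperiment-class]
#' @param fdr_threshold working FDR threshold for the `selected` flag
#' @return a [S4Vectors::DataFrame] with one row per analysed gene:
#'   `gene_id`, `rss_additive`, `rss_interaction`, `f_stat`, `p_value`,
#'   `p_adjusted`, `selected`; attributes `skipped` (character vector of
#'   skipped gene ids) and `df` (numerator/denominator dfs)
#' @export
fitInteractionModels <- function(ke, fdr_threshold = 0.05) {
  stopifnot(is(ke, "KineticExperiment"))
  design <- kineticDesign(ke)
  Y <- expressionValues(ke)
  skip <- hasMissing(ke)
  Yc <- Y[!skip, , drop = FALSE]
  Xa <- designMatrix(design, "additive")
  Xi <- designMatrix(design, "interaction")
  qa <- qr(Xa, tol = 1e-10)
  qi <- qr(Xi, tol = 1e-10)
  dfA <- nrow(Xa) - qa$rank
  dfI <- nrow(Xi) - qi$rank
  stopifnot(dfA > dfI, dfI > 0)
  rssA <- colSums(qr.resid(qa, t(Yc))^2)
  rssI <- colSums(qr.resid(qi, t(Yc))^2)
  df1 <- dfA - dfI
  tol <- 1e-10 * pmax(rssA, 1)
  f <- ((rssA - rssI) / df1) / (rssI / dfI)
  p <- pf(f, df1, dfI, lower.tail = FALSE)
  zeroI <- rssI <= tol
  p[zeroI] <- ifelse(rssA[zeroI] <= tol[zeroI], 1, 0)
  f[zeroI] <- ifelse(rssA[zeroI] <= tol[zeroI], 0, Inf)
  padj <- bhAdjust(p)
  res <- S4Vectors::DataFrame(
    gene_id = rownames(Yc),
    rss_additive = unname(rssA), rss_interaction = unname(rssI),
    f_stat = unname(f), p_value = unname(p), p_adjusted = unname(padj),
    selected = unname(padj < fdr_threshold),
    row.names = rownames(Yc))
  attr(res, "skipped") <- rownames(Y)[skip]
  attr(res, "df") <- c(df1 = df1, df2 = dfI)
  res
}

#' Select interaction genes at an FDR threshold
#'
#' Genes whose BH-adjusted nested-F p-value is strictly below the
#' threshold (adjusted p "less than" the working level), sorted by
#' adjusted p then gene id.
#'
#' @param results output of [fitInteractionModels()]
#' @param fdr_threshold threshold in `(0, 1]`
#' @return the selected subset of `results`, re-sorted
#' @export
selectInteractionGenes <- function(results, fdr_threshold = 0.05) {
  if (fdr_threshold <= 0 || fdr_threshold > 1)
    stop("fdr_threshold must be in (0, 1]")
  sel <- results[results$p_adjusted < fdr_threshold, , drop = FALSE]
  sel[order(sel$p_adjusted, sel$gene_id), , drop = FALSE]
}
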