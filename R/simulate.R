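#' Simulation parameters for synthetic kinetic experiments
#'
#' Bundles the generator settings with validation. All scales are log2
#' units. Defaults describe a realistic normalized two-colour experiment:
#' baseline levels around 8 with between-gene spread 2, effect sizes of
#' about one log2 unit (two-fold), a modest shared array effect, and
#' residual noise of half a log2 unit.
#'
#' @param n_genes number of genes
#' @param pi_interaction fraction of genes carrying a true
#'   time-by-treatment interaction, in `[0, 1]`
#' @param sigma_effect sd of drawn time, treatment and interaction effects
#' @param sigma_array sd of the per-array effect shared across genes
#' @param sigma_noise sd of the i.i.d. residual noise
#' @param missing_rate fraction of cells set to NA (default 0: the
#'   generator emits complete data)
#' @param seed integer RNG seed governing all draws
#' @return a validated list of class `SimulationParams`
#' @export
simulationParams <- function(n_genes = 2000L, pi_interaction = 0.1,
                             sigma_effect = 1, sigma_array = 0.3,
                             sigma_noise = 0.5, missing_rate = 0,
                             seed = 1L) {
  if (pi_interaction < 0 || pi_interaction > 1)
    stop("pi_interaction must be in [0, 1]")
  if (any(c(sigma_effect, sigma_array, sigma_noise) < 0))
    stop("standard deviations must be >= 0")
  if (missing_rate < 0 || missing_rate >= 1)
    stop("missing_rate must be in [0, 1)")
  structure(list(n_genes = as.integer(n_genes),
                 pi_interaction = pi_interaction,
                 sigma_effect = sigma_effect, sigma_array = sigma_array,
                 sigma_noise = sigma_noise, missing_rate = missing_rate,
                 seed = as.integer(seed)),
            class = "SimulationParams")
}

#' Simulate a kinetic dye-swap expression experiment with known truth
#'
#' Draws per-gene effects and assembles expression values exactly by the
#' interaction model `Y = mu + alpha_t + beta_p + gamma_tp + delta_a +
#' eps`: baseline `mu ~ N(8, 2)`; non-reference time effects `alpha_t`,
#' the treatment effect `beta_p`, and (for interaction genes) estimable
#' interaction effects `gamma_tp` all `~ N(0, sigma_effect)`; array
#' effects `delta_a ~ N(0, sigma_array)` drawn once per array and shared
#' across genes (they model the physical array); residuals i.i.d.
#' `N(0, sigma_noise)` per gene and observation. Interaction effects are
#' placed on the estimable interaction columns of the design (cells with
#' both factors away from reference that survive full-rank reduction);
#' non-interaction genes have `gamma = 0` identically. With
#' `sigma_noise = 0` the additive fit of a non-interaction gene
#' interpolates the data exactly.
#'
#' A single seed drives one RNG stream in a fixed draw order (truth flags,
#' then effects, then array effects, then noise, then missingness), so
#' identical parameters give identical output.
#'
#' @param params a [simulationParams()] object
#' @param design a [KineticDesign-class]; default [buildDefaultDesign()]
#' @return a [KineticExperiment-class] whose `rowData` is the truth table
#'   (`is_interaction`, `mu`, `beta`, and the drawn `alpha_*`/`gamma_*`
#'   effects)
#' @examples
#' ke <- simulateExperiment(simulationParams(n_genes = 50, seed = 7))
#' table(SummarizedExperiment::rowData(ke)$is_interaction)
#' @export
simulateExperiment <- function(params = simulationParams(),
                               design = buildDefaultDesign()) {
  stopifnot(inherits(params, "SimulationParams"))
  set.seed(params$seed)
  Xi <- designMatrix(design, "interaction")
  cn <- colnames(Xi)
  alphaCols <- grep("^time[0-9.]+$", cn)
  betaCol <- grep("^treatment", cn)
  arrayCols <- grep("^array", cn)
  gammaCols <- grep(":", cn, fixed = TRUE)
  nG <- params$n_genes
  isInt <- runif(nG) < params$pi_interaction
  # per-gene coefficient matrix in design-matrix column order
  B <- matrix(0, nrow = length(cn), ncol = nG, dimnames = list(cn, NULL))
  B["(Intercept)", ] <- rnorm(nG, mean = 8, sd = 2)
  B[alphaCols, ] <- rnorm(length(alphaCols) * nG, sd = params$sigma_effect)
  B[betaCol, ] <- rnorm(nG, sd = params$sigma_effect)
  if (length(gammaCols) && any(isInt))
    B[gammaCols, isInt] <- rnorm(length(gammaCols) * sum(isInt),
                                 sd = params$sigma_effect)
  delta <- rnorm(length(arrayCols) + 1L, sd = params$sigma_array)
  delta <- delta - delta[1L]          # reference array absorbed in mu
  B[arrayCols, ] <- B[arrayCols, ] + delta[-1L]
  Y <- t(Xi %*% B)
  Y <- Y + matrix(rnorm(length(Y), sd = params$sigma_noise), nrow = nG)
  if (params$missing_rate > 0)
    Y[matrix(runif(length(Y)) < params$missing_rate, nrow = nG)] <- NA_real_
  geneIds <- sprintf("GENE%05d", seq_len(nG))
  rownames(Y) <- geneIds
  truth <- S4Vectors::DataFrame(
    gene_id = geneIds, is_interaction = isInt,
    mu = B["(Intercept)", ], beta = B[betaCol, ],
    t(B[alphaCols, , drop = FALSE]), t(B[gammaCols, , drop = FALSE]),
    row.names = geneIds, check.names = TRUE)
  KineticExperiment(Y, design, rowData = truth)
}

#' Simulate two-group physiology measurements
#'
#' Emulates small-sample physiology endpoints (chlorophyll content,
#' respiration, photosynthesis rates): a control group `~ N(baseline,
#' sigma)` and a treated group `~ N(baseline + shift, sigma)`.
#'
#' @param n_control,n_treated group sizes (>= 2)
#' @param shift treated-minus-control location difference, measurement units
#' @param sigma within-group sd (>= 0)
#' @param baseline control group mean
#' @param seed integer RNG seed
#' @return list with numeric vectors `control` and `treated`
#' @export
simulatePhysiology <- function(n_control, n_treated, shift, sigma,
                               baseline = 0, seed = 1L) {
  if (n_control < 2 || n_treated < 2) stop("group sizes must be >= 2")
  if (sigma < 0) stop("sigma must be >= 0")
  set.seed(seed)
  list(control = rnorm(n_control, baseline, sigma),
       treated = rnorm(n_treated, baseline + shift, sigma))
}

#' Simulate a gene-to-functional-bin annotation with a planted enrichment
#'
#' Assigns each gene one bin by sampling from `proportions`; within the
#' designated `subset` the sampling weight of `enriched_bin` is multiplied
#' by `enrichment_factor`, so the planted bin's frequency in the subset is
#' about `enrichment_factor` times its background frequency (exactly so as
#' the subset grows, up to the renormalisation of the weights).
#'
#' @param gene_ids universe of gene identifiers
#' @param bins bin labels
#' @param proportions background bin probabilities, summing to 1
#' @param enriched_bin bin to over-represent within `subset`
#' @param enrichment_factor multiplicative weight (1 = no planted signal)
#' @param subset gene ids forming the enriched subset (must be in
#'   `gene_ids`)
#' @param seed integer RNG seed
#' @return data.frame (`gene_id`, `bin`), one row per gene
#' @export
simulateAnnotation <- function(gene_ids, bins, proportions,
                               enriched_bin = bins[1L],
                               enrichment_factor = 1,
                               subset = character(0), seed = 1L) {
  if (abs(sum(proportions) - 1) > 1e-8) stop("proportions must sum to 1")
  if (!enriched_bin %in% bins) stop("enriched_bin must be one of bins")
  if (!all(subset %in% gene_ids)) stop("unknown gene id in subset")
  set.seed(seed)
  w <- setNames(proportions, bins)
  wSub <- w
  wSub[enriched_bin] <- wSub[enriched_bin] * enrichment_factor
  wSub <- wSub / sum(wSub)
  inSub <- gene_ids %in% subset
  bin <- character(length(gene_ids))
  bin[!inSub] <- sample(bins, sum(!inSub), replace = TRUE, prob = w)
  if (any(inSub))
    bin[inSub] <- sample(bins, sum(inSub), replace = TRUE, prob = wSub)
  data.frame(gene_id = gene_ids, bin = bin, stringsAsFactors = FALSE)
}
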