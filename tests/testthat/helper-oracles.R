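suppressPackageStartupMessages(library(SummarizedExperiment))

# Independent oracles used across the suite. Each takes a route that is
# deliberately different from the package implementation.

# Least-squares RSS via Moore-Penrose pseudoinverse (normal equations),
# never QR.
pinvRss <- function(X, y) {
  beta <- MASS::ginv(crossprod(X)) %*% crossprod(X, y)
  sum((y - X %*% beta)^2)
}

# Upper-tail F probability by numerical integration of the F density.
fPvalQuad <- function(f, df1, df2) {
  if (!is.finite(f)) return(0)
  stats::integrate(function(x) stats::df(x, df1, df2), lower = f,
                   upper = Inf, rel.tol = 1e-12)$value
}

# Hand-rolled BH step-up: sort, multiply by n/i, cumulative min from the
# top, cap, restore order.
bhStepUp <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- p[o] * n / seq_len(n)
  adj <- rev(cummin(rev(adj)))
  pmin(adj, 1)[order(o)]
}

# P[overlap >= k] by exhaustive enumeration of all subsets of size nB
# drawn from a universe of size N, against a fixed set of size nA.
hyperUpperEnum <- function(nA, nB, k, N) {
  A <- seq_len(nA)
  picks <- utils::combn(N, nB)
  mean(apply(picks, 2L, function(s) sum(s %in% A)) >= k)
}

# Exact two-sided Mann-Whitney p by brute force over group assignments,
# computing U by pair counting (greater + half ties), not via rank sums.
mwBrute <- function(x, y) {
  pooled <- c(x, y)
  nx <- length(x)
  n <- length(pooled)
  uOf <- function(a, b) sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  uObs <- uOf(x, y)
  us <- apply(utils::combn(n, nx), 2L, function(i)
    uOf(pooled[i], pooled[-i]))
  min(1, 2 * min(mean(us <= uObs), mean(us >= uObs)))
}

# Small valid dye-swap designs (<= 12 observations) for oracle checks:
# nCmp comparisons over a 5-cell grid, each on one array (one orientation)
# so n_obs = 2 * nCmp.
toyDesign <- function(nCmp = 4L, seed = 1L) {
  set.seed(seed)
  cells <- data.frame(time_h = c(0, 2, 2, 4, 4),
                      treatment = c("control", "control", "PHN",
                                    "control", "PHN"))
  # random walk over cells keeps the comparison graph connected
  ord <- 1L
  for (i in seq_len(nCmp))
    ord <- c(ord, sample(setdiff(1:5, ord[length(ord)]), 1L))
  obs <- do.call(rbind, lapply(seq_len(nCmp), function(i) {
    a <- cells[ord[i], ]; b <- cells[ord[i + 1L], ]
    dyes <- if (i %% 2L) c("red", "green") else c("green", "red")
    data.frame(array_id = i,
               dye = dyes,
               time_h = c(a$time_h, b$time_h),
               treatment = c(a$treatment, b$treatment))
  }))
  obs <- data.frame(obs_id = sprintf("a%02d_%s", obs$array_id, obs$dye),
                    obs, stringsAsFactors = FALSE)
  methods::new("KineticDesign", observations = obs,
               comparisons = kineticDE:::.inferComparisons(obs))
}
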