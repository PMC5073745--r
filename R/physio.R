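#' Total chlorophyll from absorbances
#'
#' `Ct = 7.04 * A664 + 20.27 * A647`, in micrograms per millilitre, for
#' chlorophyll extracted in N,N-dimethylformamide and read at 664 and
#' 647 nm. Vectorised and linear in both absorbances.
#'
#' @param a664,a647 absorbance readings (>= 0)
#' @return total chlorophyll concentration, ug/ml
#' @examples
#' chlorophyllTotal(0.2, 0.1)  # 3.435
#' @export
chlorophyllTotal <- function(a664, a647) {
  if (any(a664 < 0) || any(a647 < 0)) stop("absorbances must be >= 0")
  7.04 * a664 + 20.27 * a647
}

#' Signed percent change between group means
#'
#' `100 * (treated - control) / control`, rounded half-away-from-zero.
#'
#' @param control_mean control group mean (nonzero)
#' @param treated_mean treated group mean
#' @param decimals decimal places of the rounded value
#' @return signed percent change (numeric, rounded)
#' @examples
#' percentChange(0.45, 0.73)   # 62
#' percentChange(8.74, 11.72)  # 34
#' @export
percentChange <- function(control_mean, treated_mean, decimals = 0) {
  if (control_mean == 0) stop("control mean must be nonzero")
  x <- 100 * (treated_mean - control_mean) / control_mean
  m <- 10^decimals
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# U statistic (for the first sample) from midranks of the pooled data.
.uStat <- function(ranksX, nx) sum(ranksX) - nx * (nx + 1) / 2

#' Exact Mann-Whitney rank-sum test
#'
#' Two-sample location test on ranks, with midranks for ties. For
#' combined sizes up to `exact_max` (default 20) the permutation
#' distribution of U is enumerated completely over all group
#' assignments; the two-sided p-value is `2 * min(P[U <= u], P[U >= u])`
#' capped at 1. Larger samples use the normal approximation with tie
#' correction and continuity correction.
#'
#' @param x,y numeric samples, each of size >= 2
#' @param exact_max largest combined size for exact enumeration
#' @return list: `u` (U statistic of `x`), `p_value` (two-sided),
#'   `exact` (logical)
#' @examples
#' # complete separation at sizes 5 and 6: minimal two-sided p = 2/462
#' mannWhitneyExact(1:5, 11:16)$p_value
#' @export
mannWhitneyExact <- function(x, y, exact_max = 20L) {
  if (length(x) < 2L || length(y) < 2L) stop("samples must have size >= 2")
  nx <- length(x); ny <- length(y); n <- nx + ny
  r <- rank(c(x, y))
  u <- .uStat(r[seq_len(nx)], nx)
  if (n <= exact_max) {
    idx <- combn(n, nx)
    us <- apply(idx, 2L, function(i) .uStat(r[i], nx))
    pLow <- mean(us <= u)
    pHigh <- mean(us >= u)
    p <- min(1, 2 * min(pLow, pHigh))
    return(list(u = u, p_value = p, exact = TRUE))
  }
  mu <- nx * ny / 2
  ties <- table(r)
  sig2 <- nx * ny / 12 * ((n + 1) - sum(ties^3 - ties) / (n * (n - 1)))
  z <- (u - mu - sign(u - mu) * 0.5) / sqrt(sig2)
  list(u = u, p_value = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
}

#' Two-sample t test (Welch by default)
#'
#' Welch's unequal-variance t test, two-sided; `pooled = TRUE` switches
#' to the equal-variance form. Two identical constant samples (zero
#' variance, equal means) return t = 0, p = 1.
#'
#' @param x,y numeric samples, each of size >= 2
#' @param pooled use the pooled-variance (classical) t test
#' @return list: `t`, `df`, `p_value`
#' @export
twoSampleT <- function(x, y, pooled = FALSE) {
  if (length(x) < 2L || length(y) < 2L) stop("samples must have size >= 2")
  if (sd(x) == 0 && sd(y) == 0) {
    if (mean(x) == mean(y))
      return(list(t = 0, df = length(x) + length(y) - 2L, p_value = 1))
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = length(x) + length(y) - 2L, p_value = 0))
  }
  ht <- t.test(x, y, var.equal = pooled)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p_value = ht$p.value)
}

#' Compare two measurement groups
#'
#' Convenience wrapper producing the percent change of the means plus the
#' exact Mann-Whitney (default, for small-sample endpoints) or Welch t
#' statistic.
#'
#' @param control,treated numeric measurement vectors (size >= 2)
#' @param test `"mann-whitney"` or `"t"`
#' @param decimals decimal places of the percent change
#' @return list: `n_control`, `n_treated`, `percent_change`, `statistic`,
#'   `p_value`, `test`
#' @export
compareGroups <- function(control, treated,
                          test = c("mann-whitney", "t"), decimals = 0) {
  test <- match.arg(test)
  res <- if (test == "mann-whitney") {
    mw <- mannWhitneyExact(control, treated)
    list(statistic = mw$u, p_value = mw$p_value)
  } else {
    tt <- twoSampleT(control, treated)
    list(statistic = tt$t, p_value = tt$p_value)
  }
  list(n_control = length(control), n_treated = length(treated),
       percent_change = percentChange(mean(control), mean(treated), decimals),
       statistic = res$statistic, p_value = res$p_value, test = test)
}
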