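---
title: "Models and methods in kineticDE"
author: "kineticDE authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods in kineticDE}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kineticDE)
library(SummarizedExperiment)
```

# The experiment and its design

kineticDE analyses early-response time-course experiments run on
two-colour microarrays with the dye-switch technique. The motivating
setting is a plant transcriptome probed shortly after exposure to a
xenobiotic (phenanthrene, a three-ring polycyclic aromatic hydrocarbon,
versus a DMSO control), but the machinery applies to any two-treatment
kinetic with a shared baseline.

Every observation is indexed by four coordinates: the timepoint $t$
(0, 0.5, 2, 4, 8 or 24 h), the treatment $p$ (control or PHN), the dye
$d$ (red or green) and the array $a$. Each array carries exactly two
observations with opposite dyes — the two channels of one hybridisation —
and each *comparison* (a pair of design cells hybridised against each
other) is replicated on two arrays with swapped dye orientations, which
cancels dye bias by construction.

The default design (`buildDefaultDesign()`) uses 14 comparisons:

* treated vs control at each of the five timepoints (5 comparisons);
* a consecutive-time chain through the treated arm, anchored at the
  shared baseline: 0 → 0.5 → 2 → 4 → 8 → 24 h (5 comparisons);
* a consecutive-time chain through the control arm:
  0.5 → 2 → 4 → 8 → 24 h (4 comparisons).

At $t = 0$ the treated/control distinction does not yet exist, so the
baseline is a single cell assigned to the control arm: 11 distinct
cells, 28 arrays, 56 observations, and a connected comparison graph.
The precise allocation of comparisons is one of several layouts
consistent with these totals; this one was chosen because it is the
natural kinetic layout and because it reproduces the residual degrees
of freedom quoted below, which pin down the column space of the design.

```{r design}
d <- buildDefaultDesign()
d
```

# The per-gene models and the interaction test

For each gene, two fixed-effects linear models are fitted to the 56
log2 values by ordinary least squares:

$$\text{Model 1 (additive):}\qquad
Y_{tpda} = \mu + \alpha_t + \beta_p + \delta_a + \varepsilon_{tpda}$$

$$\text{Model 2 (interaction):}\qquad
Y_{tpda} = \mu + \alpha_t + \beta_p + \gamma_{tp} + \delta_a + \varepsilon_{tpda}$$

with time effects $\alpha_t$, a treatment effect $\beta_p$, an array
effect $\delta_a$ (one coefficient per physical array), and — in
Model 2 only — a time-by-treatment interaction $\gamma_{tp}$. There is
no dye coefficient: the dye appears in the observation index only, and
dye bias is handled by the swapped orientations of the design.

Indicator columns are reference-reduced (first time level, control,
array 1). Interaction indicators are built for observed cells with both
factors away from reference; because the $t=0$/treated cell is not
observed, one of those five columns is exactly collinear with the
treatment main effect, and a greedy numerical-rank reduction removes it,
leaving the 4 estimable interaction directions. The resulting ranks are
34 (additive) and 38 (interaction), hence residual degrees of freedom

```{r df}
residualDf(d, "additive")
residualDf(d, "interaction")
```

computed from the numerical rank, never from a closed-form count.
Genes with any missing observation are excluded from fitting (and
accounted for in the run log), not imputed.

Model 1 is tested against Model 2 with the nested F statistic

$$F = \frac{(\mathrm{RSS}_1 - \mathrm{RSS}_2)/(\mathrm{df}_1 - \mathrm{df}_2)}
           {\mathrm{RSS}_2/\mathrm{df}_2},$$

referred to $F(4, 18)$ on the default design, and the per-gene p-values
are adjusted by the Benjamini–Hochberg step-up procedure. A gene is
declared to carry a time-by-treatment interaction when its adjusted
p-value is strictly below 5 % — "less than", so ties at the threshold
are not selected. Degenerate zero-residual genes are handled
conservatively: when both models interpolate the data exactly there is
no evidence for an interaction and $p = 1$; an exact interaction fit
with additive lack of fit is flagged and given the $p \to 0$ limit.

OLS is solved by QR with a relative rank tolerance of $10^{-10}$; the
indicator matrices are full-rank by construction after reference
dropping, so the tolerance only guards degenerate inputs. Across genes
the fits are vectorised: each model matrix is factorised once and
residuals for the whole gene matrix are obtained in one pass.

# Per-timepoint differential expression

Fig.-3-style per-timepoint calls use the treated-vs-control comparison
at each timepoint: within each of its two dye-swapped arrays the log2
ratio treated − control is formed per gene, and a one-sample t test of
the replicate ratios against zero is Bonferroni-corrected — a gene is
declared differentially expressed iff its raw p-value is below
$\alpha/n_\text{genes}$, with direction given by the sign of the mean
ratio (positive = higher under treatment).

The underlying per-comparison test of the original platform pipeline is
not specified beyond a citation, so the replicate t test is a documented
stand-in and the test is pluggable. With two replicates it has a single
degree of freedom and essentially no power at familywise thresholds; an
optional pooled-variance mode (a common variance estimated across genes,
with the pooled residual df) is provided and off by default. Zero
replicate variance with zero mean is not called; zero variance with a
nonzero mean is flagged degenerate and called in its direction, since
exact replicate agreement carries no internal error estimate.

# Set statistics, enrichment, clustering

**Venn partitions** of 2–5 DEG sets are exact set algebra; the
$2^n - 1$ region counts are disjoint and sum to the union size.

**Overlap significance** between two gene sets uses the upper
hypergeometric tail $P[X \ge k]$ — identical to the one-sided Fisher
exact test of the 2×2 table; one-sided because overlap enrichment is a
one-sided notion. The default universe is 22,089 genes, the gene count
of the CATMA v5 Arabidopsis array; it is configurable, and for the
published 8 h/24 h overlap (275- and 360-gene lists sharing 116 genes)
every plausible universe gives $p < 10^{-4}$.

**Functional-class enrichment** follows the Classification
SuperViewer/MapMan-bin pattern: per bin, the normalized frequency
$(k/n)/(K/N)$ and hypergeometric tails for over- and
under-representation, computed separately for up- and downregulated
sets at each timepoint. Genes may carry several bins and count once per
bin. Raw p-values at $\alpha = 0.05$ are reported by default (matching
the SuperViewer-style report); BH correction is a switch.

**Clustering** of expression profiles is agglomerative with Euclidean
distance. The linkage of the original interactive toolbox is not
stated; average linkage was chosen as the default (it is the common
default for expression profiles and robust to outliers), and the
linkage is pluggable. Trees serialize to Newick with branch lengths
derived from merge heights.

# Physiology statistics

Total chlorophyll from N,N-dimethylformamide extracts is
$C_t = 7.04\,A_{664} + 20.27\,A_{647}$ (µg·ml⁻¹). Group effects are
summarised as signed percent change of the means,
$100\,(\bar{x}_\text{trt} - \bar{x}_\text{ctl})/\bar{x}_\text{ctl}$,
rounded half-away-from-zero (62.5 → 63), which reproduces the printed
integer percentages from the printed means:

```{r physio}
percentChange(0.45, 0.73)   # chlorophyll per fresh weight
percentChange(8.74, 11.72)  # respiration per fresh weight
```

Small-sample endpoints are tested with an exact Mann–Whitney rank-sum
test: midranks for ties, complete enumeration of the permutation
distribution of $U$ for combined sizes up to 20, two-sided
$p = 2\min(\text{tails})$ capped at 1 — at sizes (5, 6) the smallest
attainable two-sided p is $2/462 \approx 0.004$, consistent with the
published `P = 0.004` entries. Larger samples fall back to the normal
approximation with tie and continuity corrections. The two-sample t
test defaults to the Welch form (the variance assumption of the
original analysis is unstated; Welch is the safer default), with a
pooled-variance toggle.

# The synthetic-data generator

`simulateExperiment()` draws per-gene effects and assembles the data
exactly by Model 2, so the generator's output lies in the model class
the fitting stage assumes:

* $\mu \sim N(8, 2)$ — a typical normalized log2 intensity scale;
* $\alpha_t, \beta_p \sim N(0, \sigma_\text{effect})$, default
  $\sigma_\text{effect} = 1$ log2 unit (about two-fold effects);
* for a fraction `pi_interaction` of genes (default 0.1), interaction
  effects $\gamma_{tp} \sim N(0, \sigma_\text{effect})$ on the
  estimable interaction directions; all other genes have
  $\gamma \equiv 0$;
* $\delta_a \sim N(0, \sigma_\text{array})$, default 0.3, drawn once
  per array and shared across genes (arrays are physical objects);
* residuals i.i.d. $N(0, \sigma_\text{noise})$, default 0.5.

The distributions and scales are the package's own choices — the
simplest exchangeable priors that make power and FDR calibration
curves meaningful; no published effect-size model exists for this
design. One integer seed drives a single RNG stream in a fixed draw
order, so runs are bit-reproducible. An optional missingness rate
(default 0: complete data) exercises the skip-and-account path.

What the generator does *not* emulate: spot-level artifacts,
intensity-dependent (loess-type) dye bias, correlated noise between
genes, and the upstream normalization itself — inputs are
post-normalization by construction. Green tests on synthetic data
therefore validate the statistical machinery, not the normalization
robustness of conclusions on real arrays.

Companion generators produce two-group physiology samples
(`simulatePhysiology()`) and gene-to-bin annotations with a planted
over-represented bin (`simulateAnnotation()`), so enrichment power and
type-I behaviour are testable end to end.

# Verification strategy and problem sizes

The test suite checks every stage against an independent route: OLS
residual sums of squares against a Moore–Penrose pseudoinverse oracle
on small random designs (≤ 12 observations), F-tail probabilities
against numerical integration of the F density, BH against a hand-rolled
step-up, hypergeometric tails against exhaustive subset enumeration on
universes ≤ 20, and the exact Mann–Whitney against brute-force
enumeration over all group assignments for all size pairs with combined
n ≤ 10. Calibration checks use 2000-gene simulations: null nested-F
p-values pass a Kolmogorov–Smirnov uniformity check, and BH selection
over 50 replicates with 10 % planted interaction genes keeps the mean
realized false discovery proportion within the nominal-plus-Monte-Carlo
margin. These sizes give stable Monte-Carlo estimates while keeping the
default test run fast.

# Known limitations

* The true allocation of the 14 comparisons in the original experiment
  is not published; the default layout is one member of the equivalence
  class fixed by the array/observation counts and the residual dfs.
* The per-timepoint test is a replicate t test standing in for the
  original platform's variance model; with two dye-swap replicates its
  per-gene form is severely underpowered, which is a property of the
  design, not of the implementation.
* Whether both biological replicates of a comparison were dye-swapped
  cannot be resolved from the text; the default assumes one array per
  orientation.
* Reproducing the published DEG counts requires the original normalized
  supplementary dataset; with `readExpression()` the pipeline consumes
  such a matrix directly, but its upstream normalization is out of
  scope here.
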