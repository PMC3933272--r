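---
title: "Scoring endogenous miRNA-mediated repression from mRNA expression"
author: "baymir package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring endogenous miRNA-mediated repression from mRNA expression}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(baymir)
```

## The problem

Sequence-based miRNA target prediction finds candidate miRNA-mRNA pairs by
locating conserved seed matches in 3'UTRs, but it cannot say whether a
candidate site is actually used under endogenous cellular conditions. When a
miRNA is active, its direct targets sit below their average expression;
a large compendium of mRNA expression profiles therefore carries a
detectable footprint of miRNA activity, with no need for matched miRNA
expression measurements.

`baymir` scores each candidate pair by asking how much of an mRNA's
down-regulation across samples is explained by the inferred activity of
that miRNA family, in the presence of all its other candidate regulators.
The unit of regulation is the miRNA *family* (miRNAs sharing a seed), since
family members are indistinguishable at the seed-match level.

## Model

For gene $i$ with candidate regulator families $k = 1 \dots K$, let
$y^i \in \mathbb{R}^M$ be its log2 expression over $M$ samples (or
biological groups). The response is the **down-regulation profile**

$$d^i = \bar{y}^i - y^i,$$

positive in samples where the gene sits below its own mean. Repression by
several miRNAs is treated as multiplicative on the linear scale, hence
additive in log2 — this is why the pipeline log-transforms before
regressing. Each family's **activity vector** is inferred from its
candidate targets (see below) and collected into $W \in \mathbb{R}^{M
\times K}$ with unit-norm columns. The scores $h \ge 0$ solve the
non-negativity-constrained elastic net

$$\hat h = \arg\min_{h \ge 0} \tfrac{1}{2}\lVert d - W h \rVert_2^2
  + \lambda_1 \sum_k h_k + \tfrac{\lambda_2}{2} \sum_k h_k^2 .$$

A positive $\hat h_k$ says family $k$'s activity helps explain the gene's
down-regulation over and above the other candidates; an exact zero is a
meaningful outcome — no expression evidence for that pair. The
non-negativity constraint encodes that miRNAs repress: an "activating"
association is treated as absence of evidence, not negative evidence.

### Sign convention

The response is the *negated* centered profile. Combining a response of
$y - \bar y$ with activity defined as the negative mean of target
expression would force genuinely repressed targets into negative
coefficients, which the $h \ge 0$ constraint forbids; regressing the
down-regulation profile instead makes repressed targets earn positive
scores, which is the interpretation the scores carry throughout.
`centerRows()` still returns $y - \bar y$ (the conventional centering);
`fitAll()` applies the negation internally.

### Penalty scaling

The objective above uses the conventional $\tfrac12$ factors, under which
the coordinate update (next section) carries $\lambda_1$ and $\lambda_2$
unscaled and the screening bound $\lambda_{\max} = \max_j |w_j^\top d|$
is exact. Writing the loss without the $\tfrac12$ merely rescales
$\lambda_1$ by two; results are identical after reparametrisation.

## Activity inference

Because miRNAs repress, samples with high activity of family $k$ show
depressed expression of its target set. With $N_k$ candidate targets,

$$w_k = -\frac{1}{N_k} \sum_{i \in \text{targets}(k)} \tilde y^i,
  \qquad w_k \leftarrow w_k / \lVert w_k \rVert,$$

where $\tilde y^i$ is by default the z-scored profile of target $i$
(`input = "zscore"`), so that high-variance genes do not dominate the
average; `"centered"` and `"raw"` variants are provided. Families with
fewer than `minTargets` (default 5) usable targets are excluded — an
average over very few profiles is noise-dominated. A gene is *not*
excluded from its own regulators' activity estimates (a leave-one-out
variant was considered and rejected as the default: with realistic target
set sizes the single-gene contribution is negligible, and keeping the
estimator simple keeps it reproducible from the network alone).

`activityExpressionCorrelation()` provides the standard diagnostic when
measured miRNA expression is available: Pearson correlation between each
inferred activity vector and the matched expression profile, against a
permutation reference.

## Solver

The objective is minimised by cyclic coordinate descent. With residual
$r = d - Wh$ and $\rho_j = w_j^\top r + h_j \lVert w_j \rVert^2$, the
exact single-coordinate minimiser subject to $h_j \ge 0$ is the one-sided
soft threshold

$$h_j \leftarrow \frac{(\rho_j - \lambda_1)_+}{\lVert w_j \rVert^2 +
  \lambda_2},$$

which equals the unconstrained elastic-net update whenever that update is
positive. Numerical choices:

* **Initialisation** $h = 0$: gives the $\lambda_{\max}$ screening
  property for free ($\lambda_1 \ge \lambda_{\max}$ returns the exact
  zero vector without an update; `lambdaMax()` uses the same summation
  order as the update so the bound holds bit-exactly).
* **Convergence**: sweeps stop when the largest absolute coefficient
  change falls below `tol`. The default `tol = 1e-8` is deliberately
  tighter than any score difference of interest so that the first-order
  (KKT) certificate — stationarity on positive coordinates,
  non-negative directional derivative on zero coordinates — holds to
  about $10^{-6}$ relative scale at the returned solution; convergence is
  geometric, so the extra sweeps cost little. `maxIter` defaults to 1000
  sweeps; non-convergence is flagged, never silently accepted.
* **Degenerate regressors**: an all-zero activity column (a family whose
  targets never move) keeps coefficient 0 and is flagged.
* The objective never increases across updates, and the solution is
  invariant (to within solver tolerance) to the coordinate sweep order;
  both are asserted in the test suite, alongside agreement with an
  independent projected quasi-Newton oracle and a non-negative lasso
  reference fit.

### Choosing the penalties

No principled values for $(\lambda_1, \lambda_2)$ exist a priori, so the
default (`lambdaSelection = "cv"`) picks one *global* pair by k-fold
cross-validation over samples: the held-out squared error is accumulated
over all genes, and ties break toward larger $\lambda_1$, then larger
$\lambda_2$ (the sparser, smoother model). The automatic grid crosses a
10-point logarithmic $\lambda_1$ path from the global $\lambda_{\max}$
down (plus 0) with $\lambda_2 \in \{0, 0.1, 1\}$. A single global pair —
rather than per-gene pairs — keeps scores comparable across genes, which
the within-family median-split evaluation relies on.

## Preprocessing

The pipeline (`preprocessExpression()`) applies, in order:

1. **Load** (`loadExpression()`): rows without a gene symbol are dropped;
   rows sharing a symbol are averaged.
2. **Group averaging**: samples of the same biological group are averaged
   (groups are highly correlated replicates of a condition). This happens
   *before* the log transform because linear-scale intensities average on
   the scale they were measured.
3. **Outlier clipping** (`clipOutliers()`): per gene, Tukey fences at the
   25th/75th percentiles with multiplier 1.5; values outside are replaced
   by the fence. Percentiles use linear interpolation between order
   statistics. A literal reading of the fence formula in terms of "second
   and fourth quartiles" (median and maximum) makes the upper fence
   unreachable and the clipping vacuous, so the quartile interpretation is
   the default and the literal variant is available as
   `literalQuartiles = TRUE`. Clipping is idempotent and monotone;
   constant rows pass through unchanged.
4. **Log2 transform**, guarded so it is applied at most once.
5. **Variance filter** (default off, `minVariance = 0`): genes whose
   expression never moves carry no regression signal; no universal
   threshold exists, so the default keeps everything and the threshold is
   exposed.

The **gene-variation index** (`geneVariation()`) is the unbiased
($n-1$ denominator) variance of each gene across samples — itself a
simple repression predictor, since miRNA-targeted genes tend to vary more
across conditions.

## Evaluation statistics

* `scoreBinResponse()`: pairs ranked by score, split into five
  equal-count bins; per-bin mean response (e.g. log-fold change after
  over-expression) with a normal-approximation 95% CI
  ($\pm 1.96\,s/\sqrt n$). Ties are broken by a stable sort on gene then
  family so the binning is deterministic.
* `medianSplitMetric()`: per family, pairs scoring strictly above the
  family median are pooled; the metric is the negative mean response of
  the pool. Families with all-tied scores have no above-median pair and
  are skipped with a warning.
* `hypergeomEnrichment()` / `categoryEnrichment()`: upper-tail
  hypergeometric (equivalently one-sided Fisher) tests with
  Benjamini-Hochberg correction, applied per family across its
  categories by default (`poolFamilies = TRUE` pools all tests); the
  enrichment flag uses an FDR cutoff of 0.1. The default universe is the
  genes in the score table; whether to widen it to all assayed genes is
  left to the caller, as the choice changes the null.
* `positionScoreAssociation()`: each scored pair maps to its most extreme
  site (largest $|L - 0.5|$, where $L$ is site start over 3'UTR length —
  pairs, not sites, carry scores, and terminal placement is the feature
  of interest). Classes use strict thresholds ($L < 0.25$ near-ORF,
  $L > 0.75$ near-poly(A), otherwise middle). Rank-sum comparisons use
  exact enumeration for groups of at most 10 without ties, and the normal
  approximation with tie correction otherwise.

## The synthetic-data generator

`simulateBundle()` generates the full input set with the statistical
structure the model assumes, plus the planted truth needed for recovery
tests:

* **Activities**: per family, a low-order random Fourier series over the
  sample axis — smooth, as biological-group structure is — then centered,
  orthonormalised and sign-aligned. Orthogonality makes the per-gene
  regression identifiable by construction, so recovery failures indicate
  method limits rather than ill-posed simulations.
* **Network**: each (gene, family) pair is a candidate edge with
  probability `edgeDensity = 0.1`, matching the order of magnitude of
  conserved seed-match incidence in genome-scale candidate networks.
* **Coefficients**: each candidate edge is functional with probability
  `fracFunctional = 0.6` (roughly the fraction of candidate duplexes
  with a detectable endogenous down-regulation signal); functional edges
  draw $h \sim \text{Exp(mean = 2)}$ on the log2 scale. With unit-norm
  activities over 100 samples this yields typical per-sample effects of
  ~0.2 log2 units and strong-target extremes of 0.5–1 log2 units,
  the magnitude range seen in transfection assays. The exponential gives
  the heavy-ish tail needed for meaningful score binning.
* **Expression**: $\text{log2 expr} = \text{baseline} - C A^\top +
  \varepsilon$ with baseline $\sim N(8, 1)$ (cosmetic; array-like
  intensities) and i.i.d. Gaussian noise, `noiseSd = 0.25` by default.
* **Sites**: one site per edge, uniform relative position, 3'UTR lengths
  300–3000 nt; `positionBoost` optionally inflates coefficients of
  terminally-sited edges for positional-association tests.
* `simulateOverexpression()` mimics a transfection assay: response
  $= -\text{effectScale} \cdot h + \text{noise}$ for every gene, noise
  only where no functional edge was planted.

The reference bundle used throughout the tests is 500 genes, 20 families,
100 samples, noise sd 0.25, seed 1 — small enough that the whole suite
runs in well under a minute of solver time, large enough that recovery
statistics are stable.

What the generator deliberately does **not** emulate: probe effects,
batch structure, correlated noise, miRNA co-expression, expression-level-
dependent variance, or any sequence-level feature beyond site position.
Passing recovery tests therefore demonstrates correctness of the
machinery under the model's own assumptions, not performance on real
arrays.

## Known limitations

* **Activity leakage.** A target's profile carries the planted effects of
  *all* its regulators, and averaging over a family's targets does not
  remove the components contributed by other families — they are
  systematic, not independent noise. Inferred activity vectors are
  therefore contaminated mixtures, and candidate edges with no planted
  effect can acquire positive scores when their family's inferred vector
  overlaps an activity that genuinely represses the gene. On the
  reference bundle this is the dominant error source: ranking among truly
  functional pairs is barely affected, but the separation of functional
  from non-functional candidate edges is visibly weaker with inferred
  activities than with the planted ones, and increasing the L1 penalty
  does not repair it (sparsity removes weak true edges at least as fast
  as leaked ones). This is inherent to mean-of-targets activity
  estimation, not to the solver.
* The model is linear in activities; saturating or cooperative repression
  is outside it.
* Scores are conditional on the supplied candidate network: a missing
  edge can never be scored, and a wrong edge competes for variance.
* With more regulators than samples the elastic net still yields a
  solution, but individual coefficients become unstable; such genes are
  fit anyway and can be recognised by their regulator counts.
* The activity-expression correlation diagnostic requires externally
  supplied miRNA expression; the package ships no repository access.
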