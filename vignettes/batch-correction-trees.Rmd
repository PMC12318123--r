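---
title: "Hierarchical batch-effect correction of incomplete omics data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Hierarchical batch-effect correction of incomplete omics data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(batchtree)
```

## The problem

Quantitative omics profiles (bottom-up proteomics, metabolomics, micro-array
transcriptomics) acquired in separate runs or studies carry systematic
technical biases — batch effects — that must be removed before the data can
be compared. Two practical obstacles dominate at scale. First, omics
matrices are incomplete: a protein quantified in one batch is often entirely
absent from another, and imputation is unreliable when the missingness
mechanism is unknown. Second, the standard correctors (the empirical-Bayes
location/scale adjustment popularised as ComBat, and linear-model batch
removal as in limma) require every batch to contribute at least two numeric
values per feature, which whole-matrix application of either method cannot
guarantee on incomplete data without discarding large parts of it.

This package integrates any number of batches by decomposing the task into a
**binary tree of pairwise correction steps**. At each level, adjacent
batches are paired, corrected against each other, and merged; an odd batch
is carried to the next level. For `N` batches the tree performs exactly
`N - 1` pairwise steps, so the work grows linearly in the number of batches.
Within a pair, a feature is

* **corrected** when it has at least two numeric values in both batches,
* **propagated** unchanged when one batch has no numeric values for it
  (there is no second batch to compare against — the batch effect is
  unidentifiable at this step, and a later level may supply the comparison),
* **absent** when neither batch observes it.

Because propagation is lossless, the only data ever discarded is removed by
a single pre-processing pass (*singleton removal*) that blanks any
(feature, batch) block holding exactly one numeric value — such lone values
support neither a location nor a scale estimate. Merging two batches can
only increase per-feature counts, so blocks that satisfy the
0-or-at-least-2 rule per input batch satisfy it for every merged
intermediate batch as well; the pass therefore runs once, on the input
batches, and re-screening intermediate batches would be a no-op (this is
verified by an idempotence test rather than assumed).

## The model and the three adjusters

All back-ends share the location/scale (L/S) model for the log-scale
intensity of feature $f$ in sample $j$ of batch $i$:

$$y_{ijf} = \alpha_f + X\beta_f + \gamma_{if} + \delta_{if}\,\varepsilon_{ijf},$$

with overall expression $\alpha_f$, categorical covariates encoded in the
design matrix $X$ with coefficients $\beta_f$, additive batch effect
$\gamma_{if}$, multiplicative batch effect $\delta_{if} > 0$, and
standard-normal noise $\varepsilon$.

**Empirical-Bayes location/scale (`method = "combat"`).** The parametric
variant: per feature, $\hat\alpha_f$, $\hat\beta_f$ and a pooled residual
variance are estimated by least squares; the data are standardized; per
batch, location and scale estimates are shrunk toward a normal and an
inverse-gamma prior whose hyperparameters come from method-of-moments fits
across features; the iterative posterior solution stops at an absolute
change below 1e-6 or 100 iterations (fixed so results are reproducible to
float tolerance). Non-parametric priors and mean-only mode are out of
scope.

**Linear model (`method = "limma"`).** Per feature, ordinary least squares
of the observed values on intercept + batch + covariates; only the fitted
batch term is subtracted, so covariate and intercept contributions are
retained.

**Reference-based (`references = TRUE`).** When conditions are known only
for a few samples, those are flagged as references; the batch shift is
estimated by least squares on the references alone and the same per-batch
shift is subtracted from *all* samples. Eligibility then additionally
requires two numeric reference values per batch (mirroring the general
rule; the threshold is this package's choice). Covariate mode and
reference mode are mutually exclusive.

Missing values are handled identically everywhere: every sum, mean and
variance runs over observed entries only, with per-feature per-batch
observed counts replacing $n$ in each estimator. Features are grouped by
their observation pattern so that each distinct pattern is solved in one
vectorized least-squares call.

Numerical conventions worth knowing:

* Batch indicators use **sum-to-zero coding**, so a pairwise step
  distributes the shift symmetrically over both batches instead of
  designating a reference batch; batch-swap invariance is then exact. Any
  global constant offset is irrelevant for downstream analyses that use
  relative differences (differential expression, classification,
  clustering), and per-feature z-scoring removes it entirely.
* A covariate level perfectly confounded with batch makes the design
  rank-deficient; this raises an error naming the offending column rather
  than silently dropping the covariate.
* Features with (numerically) zero pooled residual variance in a pair are
  propagated with a warning — their scale adjustment is undefined. The
  zero test uses a scale-aware tolerance of `1e-12 * (1 + mean(y^2))`
  because exact zeros surface as ~1e-31 after the QR fit.
* Empirical-Bayes priors need at least two eligible features with
  variation across features; toy inputs below that limit raise an error.

### Order invariance

For the linear adjuster, a pairwise step maps every sample to its
within-batch deviation plus the unweighted mean of the two batch means; by
induction over tree levels, the final output is the within-batch deviation
plus one per-feature constant that depends on the tree shape. Reordering
the input batches therefore changes the corrected matrix only by
per-feature constant offsets, which cancel in all between-sample distances
— label ASW agrees to ~1e-16 in practice. The empirical-Bayes adjuster
rescales variances per pair, and rescaling does not commute across tree
shapes: its outputs under different batch orders differ by more than
offsets (per-feature standard deviations of the difference around 0.1–0.3
on typical simulated data). The order-invariance experiment records both;
only the linear adjuster's invariance is asserted.

## Scheduling (P, R, S)

Steps within a tree level touch disjoint samples and are data-parallel. The
schedule assigns each level a worker-pool size: initially `workers` (P),
divided by `reduction` (R, floored, minimum 1) after every level, and
forced to 1 once the number of active batches is at most `seq_threshold`
(S). Execution uses a fork-based process pool. The schedule is a pure
function of the plan and the parameters, and because every step is
deterministic, P/R/S can never change numeric output — a contract the test
suite checks by comparing corrected matrices across schedules.

## Quality control

Integration quality is summarized by the average silhouette width (ASW):
the mean over samples of $(b_i - a_i)/\max(a_i, b_i)$, where $a_i$ is the
mean distance to the sample's own group and $b_i$ the smallest mean
distance to another group. Computed against the batch of origin, lower
values after correction indicate better mixing; against a biological
label, higher values indicate better-preserved signal. Members of
singleton groups contribute 0, and samples with a missing grouping value
are excluded and counted.

Distances on incomplete data are pairwise-complete Euclidean distances
rescaled by $\sqrt{F_{\text{total}}/F_{\text{shared}}}$, so that pairs
sharing fewer features remain comparable; a sample pair sharing no
observed feature is an error. This convention is isolated in
`omics_dist()` so it can be swapped; published tools do not document their
choice, which is why cross-tool ASW comparisons should allow small
tolerances.

## The simulator

`simulate_batches()` draws data directly from the L/S model:
$\alpha_f, \beta_f, \gamma_{if}$ standard normal, $\delta_{if}$
inverse-gamma with shape 5 and scale 2 (density $\propto
x^{-\text{shape}-1} e^{-\text{scale}/x}$, mean $\text{scale}/(\text{shape}-1)
= 0.5$), $\varepsilon$ standard normal. Missingness is feature-wise MCAR:
per batch, a uniformly random fraction of features is blanked entirely, so
no partial blocks (and hence no singletons) are introduced. Class
imbalance assigns condition proportions per batch with the minority
condition randomized per batch; `simulate_imbalanced_pair()` builds the
symmetric two-batch depletion design (condition 1 depleted in batch 1,
condition 2 in batch 2) with optional reference flagging, one reference
per condition.

What the simulator deliberately does **not** emulate: missing-not-at-random
censoring at detection limits, correlated features, non-normal noise, and
real acquisition artifacts. Passing tests on this generator demonstrate
correctness of the estimators under the generative model they assume, not
performance on arbitrary real data.

## Desk-scale experiments and chosen problem sizes

The `sweep_*`/`check_*`/`compare_*` drivers reproduce the simulation
designs at sizes chosen to keep a full run in seconds-to-minutes on one
CPU, with the full-scale configuration (6000 features, 20 batches of 10
samples, 10 repetitions) reserved for the tree-versus-one-step equivalence
comparison, which is cheap. The test suite uses 2000 features for the
covariate-rescue scenario (8 batches of 80 samples) and the published
600-feature configuration for the reference-imbalance sweep; `fast = TRUE`
variants (3 repetitions, 1000–2000 features) exist for quick iteration.
Repetition summaries are reported as means over 10 repetitions, matching
how the underlying experiments are usually presented; experiment records
carry their seeds so every summary is recomputable. Elapsed times are
recorded but never asserted — wall-clock numbers are hardware-dependent.

One observation from the reference-mode experiment is worth stating
explicitly: with only two references per batch, the residual per-feature
batch offset left by reference-estimation noise (standard deviation about
$\delta/\sqrt{2}$) aligns increasingly with the label as imbalance grows,
so the label ASW of the reference mode drifts slightly *upward* rather
than staying perfectly flat. It never degrades — which is the property
that matters — and the drift shrinks with more references.

## Limitations

* Only categorical covariates are supported; continuous covariates are out
  of scope, as are count models for sequencing data.
* The empirical-Bayes adjuster requires enough features (and variation
  across them) to estimate priors; it is not meant for single-feature use.
* Reference-based correction estimates location shifts only; it does not
  adjust scale differences between batches.
* ASW is one global metric; users should corroborate integration quality
  with additional metrics and downstream analyses.

## A worked example

```{r example}
sim <- simulate_batches(n_features = 1000, n_batches = 6,
                        samples_per_batch = 10, missing_fraction = 0.2,
                        seed = 42)
fit <- batchtree(sim$values, sim$meta, method = "combat")
fit
glance(fit)
tidy(fit)
```

The QC report shows full value retention (no singletons exist under
feature-wise MCAR), batch ASW dropping toward zero and label ASW rising —
batch structure removed, biological signal exposed.
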