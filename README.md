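# batchtree

Hierarchical, missing-value-tolerant batch-effect correction for
feature-by-sample omics matrices (proteomics, metabolomics, micro-array
transcriptomics), for analysts who need to integrate many independently
acquired datasets without imputing.

## What it does

Omics matrices assembled from several batches are incomplete: features
quantified in one batch are often entirely missing from another. The
standard correctors — the empirical-Bayes location/scale adjustment
(ComBat-style) and linear-model batch removal (limma-style) — require at
least two numeric values per feature in every batch, which a whole-matrix
application cannot guarantee without discarding data.

`batchtree` integrates `N` batches through a **binary tree of pairwise
correction steps** (exactly `N - 1` steps, linear in the number of
batches). Each step corrects the features with at least two numeric values
in both batches of the pair under the location/scale model

    y_ijf = alpha_f + X beta_f + gamma_if + delta_if * eps_ijf

(additive batch effect `gamma`, multiplicative batch effect `delta`,
categorical covariates in `X`), and **propagates** all other features
unchanged to the next level — no values are lost beyond an initial
singleton-removal pass that blanks (feature, batch) blocks holding exactly
one numeric value. Three back-ends are available: parametric
empirical-Bayes location/scale (`method = "combat"`), per-feature OLS with
the batch term subtracted (`method = "limma"`), and a reference-sample mode
(`references = TRUE`) for designs where conditions are known only for a few
flagged samples. Quality is reported as average silhouette width (ASW) with
respect to batch (lower after correction = better mixing) and biological
label (higher = better-preserved signal), using pairwise-complete rescaled
Euclidean distances. A generative simulator and scripted experiments
(missingness sweep, batch-count scaling, covariate rescue under class
imbalance, reference-mode robustness, batch-order invariance) make every
claim testable.

## Worked example

```r
library(batchtree)

sim <- simulate_batches(n_features = 1000, n_batches = 6,
                        samples_per_batch = 10, missing_fraction = 0.2,
                        seed = 42)
fit <- batchtree(sim$values, sim$meta, method = "combat")
fit
#> batch-effect correction tree fit (combat)
#>   1000 features x 60 samples, 6 batches, 5 pairwise steps
#>   numeric values: 48000 in, 0 removed in pre-processing, 48000 out
#>   ASW batch: 0.3759 -> -0.0610
#>   ASW label: 0.1576 -> 0.4177
#>   elapsed: 0.06 s (correction phases only)
```

Before correction the samples cluster by batch (ASW batch 0.38); afterwards
batch structure is gone (-0.06) while the two simulated biological
conditions separate clearly (ASW label 0.16 -> 0.42). All 48,000 numeric
values are retained — under feature-wise per-batch missingness there are no
singleton values to remove. `tidy(fit)` lists each pairwise step with the
number of features corrected, propagated and absent; `glance(fit)` returns
the one-row QC summary; `autoplot(fit)` plots the ASW panel.

A command-line front end wrapping the same functions lives at
`inst/cli/batchtree.R`:

```sh
Rscript inst/cli/batchtree.R simulate --features 2000 --batches 8 --samples 10 \
    --missing 0.2 --out-matrix M.tsv --out-meta meta.tsv --seed 7
Rscript inst/cli/batchtree.R run --matrix M.tsv --meta meta.tsv \
    --method limma --label-col label --procs 4 --out out/
Rscript inst/cli/batchtree.R qc --matrix out/corrected_matrix.tsv \
    --meta meta.tsv --label-col label
```

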