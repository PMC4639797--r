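---
title: "Transcriptomic age from multi-cohort blood expression: models and design"
author: "txage"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Transcriptomic age from multi-cohort blood expression: models and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(txage)
```

## The problem

Whole-blood gene expression changes with chronological age: a sizeable
minority of genes drift up or down roughly linearly across adulthood. Three
questions follow. Which genes move with age, robustly across independent
cohorts measured on different arrays? Is that movement transmitted through
DNA methylation at nearby CpG sites? And can the expression profile of one
person be compressed into a single "transcriptomic age", whose deviation
from chronological age (delta age) behaves like a marker of biological
ageing — correlating with blood pressure, lipids, glucose, BMI?

`txage` implements that full analysis as a reusable pipeline, and ships a
synthetic multi-cohort generator with the statistical structure the analysis
assumes, so every stage can be exercised and scored against known truth
without any external data.

## Per-cohort association models

Within each cohort, expression is quantile-normalized to the median
distribution, log2-transformed and standardized; the association model is
ordinary least squares of standardized expression on chronological age with
the confounders in the model (sex, fasting, smoking, cell counts, plate,
RNA quality). The t-statistic of the age coefficient is converted tail-wise
to a z-score, `z = sign(t) * qnorm(P(T_df > |t|))`, computed on the log
scale so statistics as extreme as |z| ≈ 37 survive without underflow;
two-sided p-values are floored at 1e-300. Exact fits (zero residual) cap at
the floor rather than propagating infinities.

For the methylation analyses two companion regressions are fitted per
CpG–gene pair within 250 kb: Model 1 regresses methylation beta-values on
age (methylation-side covariates: sex, fasting, smoking, cell counts, chip
and row where available) and Model 2 regresses expression on methylation
plus age (expression-side covariates: plate, RNA quality). All fits use the
Frisch–Waugh partial-regression route, so a cohort's thousands of units cost
two matrix residualizations and one cross-product.

## Meta-analysis and gating

Per-unit cohort statistics are combined by the sample-size-weighted z-score
(Stouffer) scheme: `z_meta = sum(w_i z_i)` with `w_i = sqrt(n_i) /
sqrt(sum n_j)`, so squared weights sum to one. Cohorts missing a unit
contribute `?` to the direction string and are dropped from the weights.
The expression–age meta combines z-scores; the methylation metas combine
t-statistics (the weighted-sum-of-t convention of the original analyses) —
with hundreds of residual degrees of freedom the distinction is cosmetic,
but it is preserved.

Gating mirrors a discovery/replication design: discovery-significant units
are those with `p < 0.05/m` where `m` is the number of units actually tested
in the run (never a hard-coded constant); replication requires
`p < 0.05/m_repl` over the replication cohorts *and* the same sign as the
discovery z; a final combined meta re-ranks the replicated units over all
cohorts.

## Mediation

For each pair, the Sobel statistic combines the two meta z-scores,

`z_sobel = z1 * z2 / sqrt(z1^2 + z2^2)`,

with `|z_sobel| <= min(|z1|, |z2|)` algebraically; it is defined as 0 when
either input is 0. Flags apply a per-gene Bonferroni rule: a pair is a
mediator if its Sobel p beats `0.05 / (CpGs tested in that gene)`. The Sobel
test is conservative under the null, which the test suite documents
directly. Enrichment of flagged mediators in annotation classes (enhancer,
insulator, promoter; island/shore/shelf/open sea) uses Fisher's exact test
for the p-value, with the sample odds ratio and a Woolf confidence interval
(Haldane–Anscombe 0.5 correction when a cell is empty), and a companion
alpha-grid curve from 1e-20 to 0.05 for robustness. Matched control genes
are chosen from the least-associated pool by greedy nearest-neighbour
matching on standardized (log length, log mean expression) with a
pairwise-swap refinement; the operative contract is covariate balance
(two-sample KS at alpha 0.01), which the suite checks.

Boundary conventions, where the field is silent, are fixed and tested:
coordinates are 0-based half-open throughout; the CpG window is closed at
`start - 250 kb` and open at `end + 250 kb`; shore/shelf boundaries at
exactly 1,500 bp close toward the island.

## The predictor

The predictor never touches individual-level training data; it is built
from summary statistics. Meta z-scores convert to standardized marginal
effects via the standardized-regression identity

`b = z / sqrt(z^2 + n - 2)`  (s.d. of age per s.d. of expression),

and joint effects solve the ridge system assembled from a reference
correlation matrix `R` (the sample-size-weighted average of per-cohort
expression correlation matrices, diagonal reset to 1):

`b_R = ((n - 1) R + lambda I)^-1 (n - 1) b`,

using `X'X ≈ (n - 1) R` for standardized probes — the best linear unbiased
prediction construction from marginal effects. The system is solved by
Cholesky, never explicit inversion; `n` is the sample-size-weighted mean of
the contributing cohort sizes (the pooling convention is a design choice;
results are insensitive to it at the scales used). The suite pins this
construction to an independent oracle: on one cohort, the summary-statistic
solution equals explicit individual-level ridge `(X'X + lambda I)^-1 X'y`
to 1e-8.

`lambda` is calibrated by grid search (default 25 log-spaced points on
[1, 1e6]) maximizing Pearson r between predictor and age in a designated
calibration cohort that is excluded from the meta-analysis and from `R`;
ties take the smallest lambda. Validation is leave-one-cohort-out: each
cohort is scored by a model assembled entirely from the others, the raw
predictor `Z = sum_i b_R(i) x_i` is rescaled to the left-out cohort's age
moments, and delta age is `SZ - age`. The exported general predictor uses
all cohorts except the calibration cohort and carries pooled training
constants (pooled age mean/s.d. via the within-plus-between pooled-variance
formula, predictor moments over the pooled training samples) so that a
cohort without age data can still be scored in years. For leave-one-out
validation the scaling constants come from the validation cohort itself;
this asymmetry follows the two use cases rather than a single convention.
Genes absent from a scored cohort are dropped without renormalizing the
remaining weights (the weights are absolute); scoring aborts if gene
overlap falls below 90%.

## What the generator emulates — and what it does not

Each cohort draws chronological age uniformly on [20, 80] years (recorded
to two decimals) and a latent per-sample ageing offset `Normal(0, 5 y)`.
The *effective* age (chronological + offset) drives expression: 20% of
1,000 genes carry an effect of 0.3 expression-s.d. per s.d. of effective
age with random sign, on top of sex, plate-batch and RNA-quality effects
and unit Gaussian noise, around gene-specific mean log2 intensities. The
offset is the device that makes delta age biologically meaningful:
phenotypes are `intercept + slope*age + coupling * sd_pheno * offset +
noise`, with coupling 0.1 phenotype-s.d. per year by default, so a person
whose transcriptome "runs old" also runs high on blood pressure, lipids,
glucose and BMI — and with coupling 0 the delta-age association is exactly
null, which the suite uses for calibration checks.

Methylation is generated on the logit scale and mapped through the inverse
logit, keeping beta-values in [0, 1] while preserving an approximately
linear age signal. Half of the age genes (by default) get one mediating
CpG: its logit methylation correlates 0.6 with effective age, and the
gene's expression is rewritten so that `mediation_strength` of its age
effect flows through that CpG — the marginal age effect is unchanged, which
is what makes Model-2 attenuation and the Sobel construction well-posed.
Mediating CpGs are preferentially labelled enhancer/insulator and
non-island; 30% of non-mediating CpGs drift with age (correlation 0.4)
without touching expression, mimicking the genome-wide abundance of
age-associated methylation. Gene windows sit on one synthetic chromosome,
spaced so windows never overlap (multi-gene CpG assignment is still
exercised by dedicated interval tests).

Not emulated: probe-level array artifacts (cross-hybridization, dye bias),
realistic spatial correlation between neighbouring CpGs, non-uniform age
distributions, cohort-specific covariate availability, and platform
harmonization. Passing tests therefore demonstrate the statistical
machinery under its stated assumptions — linear effects, Gaussian noise,
independent sites — not robustness to real-array pathology.

## Numerical choices and problem sizes

Default study conditions are 6 cohorts × 500 samples × 1,000 genes × 5
CpGs/gene — large enough that meta z-scores, ridge solves and LOO folds
behave as in a full-scale analysis, small enough that the entire pipeline
runs in seconds. Effect sizes were chosen once for testability: no
published effect-size distribution exists for the real gene set. The
replicated-gene set is scored against generator truth (observed false
discovery proportion is reported by the pipeline). The test suite runs its
replicate-based checks at stated sizes: leave-one-out recovery over 20
seeds at the full default conditions; the phenotype-coupling check at 4
cohorts × 400 samples × 400 genes (20 coupled seeds, 60 null seeds); the
enrichment-direction check at 3 cohorts × 200 samples × 200 genes × 5
CpGs/gene over 20 seeds.

Other fixed choices: centering alternates row/column sweeps to 1e-10 (at
most 100 iterations); all sample s.d.s use the n−1 denominator (this is
what makes `X'X = (n-1) R` exact for standardized columns); factors expand
to treatment-coded indicators; samples with missing covariates are dropped
per fit with a logged count; phenotype outliers are excluded by the
`|value - median| > 4 * MAD` rule before fitting; collinear
methylation–age pairs (|r| > 0.999) and zero-variance units are flagged
`NA`/`?` rather than fitted.

## Known limitations

The ridge approximation inherits the quality of `R`: with few or small
reference cohorts, `lambda` absorbs the sampling noise of `R` and the
calibrated value can sit at the top of the grid — harmless for correlation
with age (the predictor is scale-free) but meaningful if absolute weights
are compared across runs. The Sobel test is conservative; counts of flagged
mediators should be read as lower bounds. Greedy-plus-swap matching is not
globally optimal matching; its balance contract, not optimality, is the
guarantee. The pipeline's discovery/replication split of the synthetic
cohorts is positional (first `n - 2` cohorts discover, the rest replicate)
and configurable, not data-driven.

## A short run

```{r example, eval = FALSE}
cfg <- sim_config(n_cohorts = 4, n_per_cohort = 200, n_genes = 200,
                  seed = 11)
res <- run_pipeline(cfg)
res$summary$n_replicated        # replicated age-associated genes
res$prediction$r_by_cohort      # leave-one-out r(SZ, age) per cohort
res$summary$enhancer_or         # mediator enrichment in enhancers
res$phenotypes$meta             # delta-age association meta-analysis
```
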