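# txage

Multi-cohort analysis of age-associated blood gene expression, and a
"transcriptomic age" predictor built from summary statistics.

Blood transcriptomes drift with age. Given per-cohort sample-by-gene
expression matrices with covariates — and, optionally, CpG methylation and
phenotype tables — `txage` answers three questions the way a large
consortium study would:

1. **Which genes move with age?** Per-cohort least-squares models of
   standardized expression on chronological age (confounder-adjusted),
   combined by sample-size-weighted z-score meta-analysis
   (`z_meta = Σ wᵢzᵢ`, `wᵢ = √nᵢ/√Σnⱼ`), with Bonferroni
   discovery/replication gating and direction-agreement rules.
2. **Is the effect methylation-mediated?** For CpG sites within 250 kb:
   Model 1 (methylation ~ age), Model 2 (expression ~ methylation + age),
   Sobel statistic `z₁z₂/√(z₁²+z₂²)` on the meta z-scores with per-gene
   Bonferroni flags, matched control genes, and Fisher-exact enrichment of
   mediators in chromatin features (enhancer/insulator/promoter,
   island/shore/shelf).
3. **How old does a transcriptome look?** A ridge/BLUP predictor assembled
   purely from summary statistics: marginal effects `b = z/√(z²+n−2)`,
   joint effects `b_R = ((n−1)R + λI)⁻¹(n−1)b` with a sample-size-weighted
   reference correlation matrix `R`, λ calibrated on a held-out cohort,
   leave-one-cohort-out validation, rescaling to age units (`SZ`), delta
   age `SZ − age`, and delta-age/phenotype association models.

A synthetic multi-cohort generator (`sim_config()`, `simulate_cohorts()`,
`simulate_methylation()`, `simulate_phenotypes()`) produces data with the
structure the analysis assumes — including a latent per-sample ageing-rate
offset that couples expression and phenotypes — plus full truth tables, so
every downstream discovery can be scored. See the vignette
(`vignettes/transcriptomic-age.Rmd`) for the models, assumptions and design
choices.

## Worked example

```r
library(txage)
cfg <- sim_config(n_cohorts = 4, n_per_cohort = 200, n_genes = 200,
                  frac_age_genes = 0.2, n_cpg_per_gene = 4, seed = 11)
res <- run_pipeline(cfg)
str(res$summary[c("n_discovery_significant", "n_replicated",
                  "replicated_fdr", "loo_r_min", "mean_abs_delta_age",
                  "enhancer_or", "island_or")])
#> List of 7
#>  $ n_discovery_significant: int 38
#>  $ n_replicated           : int 38
#>  $ replicated_fdr         : num 0
#>  $ loo_r_min              : num 0.802
#>  $ mean_abs_delta_age     : num 8.15
#>  $ enhancer_or            : num 7.1
#>  $ island_or              : num 0.448
```

Reading: of 200 simulated genes (40 truly age-associated), 38 pass the
discovery Bonferroni gate and all 38 replicate, with none a false
discovery (`replicated_fdr = 0`). Leave-one-out transcriptomic age
correlates with chronological age at r ≥ 0.80 in every left-out cohort,
with a mean absolute gap of ~8.2 years between predicted and chronological
age. Sobel-flagged mediating CpGs are strongly enriched in enhancers
(OR ≈ 7.1) and depleted in CpG islands (OR ≈ 0.45), matching the planted
regulatory structure. `res$phenotypes$meta` holds the delta-age/phenotype
meta-analysis (positive z for blood pressure, lipids, glucose, BMI when
coupling is on).

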