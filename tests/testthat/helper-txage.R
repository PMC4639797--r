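# small configurations used across test files
tiny_cfg <- function(...) {
  args <- list(...)
  defaults <- list(n_cohorts = 2, n_per_cohort = 120, n_genes = 80,
                   n_cpg_per_gene = 2, seed = 42L)
  do.call(sim_config, utils::modifyList(defaults, args))
}

# critical |r| for a two-sided t-test at level alpha with n samples
r_critical <- function(n, alpha = 0.05) {
  tc <- stats::qt(1 - alpha / 2, n - 2)
  tc / sqrt(tc^2 + n - 2)
}
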