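#' Run the full synthetic-data analysis pipeline
#'
#' One call that mirrors the whole study design on generated data:
#' simulate cohorts (expression, methylation, phenotypes) -> residualize ->
#' per-cohort expression-age models -> Stouffer meta-analysis with
#' discovery/replication/combined gating -> methylation mediation (Models 1
#' and 2, Sobel, per-gene Bonferroni flags, feature enrichment) ->
#' summary-statistic ridge predictor with leave-one-out validation, delta
#' age, and delta-age/phenotype meta-analysis. Deterministic under
#' `config$seed`.
#'
#' @param config a [sim_config()].
#' @param n_discovery number of cohorts in the discovery stage (the rest
#'   replicate); default all but two, minimum one of each.
#' @param lambda ridge penalty; `NULL` calibrates on the first cohort over
#'   the default grid.
#' @param run_mediation run the methylation/mediation stage (needs
#'   `n_cpg_per_gene > 0`).
#' @param out_dir optional directory; when given, per-cohort TSVs, meta
#'   tables and the summary JSON are written there.
#' @return list with elements `meta` (discovery/replication/combined tables,
#'   gating), `mediation` (sobel table, flags, enrichment), `prediction`
#'   (per-cohort predictions, lambda, per-cohort r), `phenotypes` (delta-age
#'   association meta), and `summary` (flat named list, JSON-serializable).
#' @export
run_pipeline <- function(config = sim_config(), n_discovery = NULL,
                         lambda = NULL, run_mediation = TRUE,
                         out_dir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  sim <- simulate_cohorts(config)
  med_sim <- if (run_mediation && config$n_cpg_per_gene > 0)
    simulate_methylation(config, sim$cohorts, sim$genes)
  else list(cohorts = sim$cohorts, cpgs = NULL)
  cohorts <- simulate_phenotypes(config, med_sim$cohorts)
  genes <- sim$genes
  cohort_ids <- vapply(cohorts, `[[`, character(1), "cohort_id")

  if (is.null(n_discovery))
    n_discovery <- max(1L, length(cohorts) - 2L)
  stopifnot(n_discovery >= 1, n_discovery < length(cohorts))
  disc_idx <- seq_len(n_discovery)
  repl_idx <- setdiff(seq_along(cohorts), disc_idx)

  adjust <- c("sex", "fasting", "smoking", "gran", "lymph", "mono", "ery",
              "plt", "plate", "rna_quality")
  # prediction stage works on standardized residuals; the association stage
  # fits standardized expression with the confounders in the model itself
  prepped <- lapply(cohorts, prepare_cohort, adjust = adjust)
  std <- lapply(cohorts, function(co)
    residualize(co$expression, co$covariates, character()))

  # --- association + meta with gating -----------------------------------
  age_stats <- lapply(seq_along(cohorts), function(k)
    fit_age_model(std[[k]], cohorts[[k]]$covariates, adjust = adjust,
                  cohort_id = cohort_ids[k]))
  disc_stats <- do.call(rbind, age_stats[disc_idx])
  repl_stats <- do.call(rbind, age_stats[repl_idx])
  meta_disc <- stouffer_meta(disc_stats, cohorts = cohort_ids[disc_idx])
  sig_disc <- gate_discovery(meta_disc, m = nrow(meta_disc))
  meta_repl <- stouffer_meta(
    repl_stats[repl_stats$unit_id %in% sig_disc, , drop = FALSE],
    cohorts = cohort_ids[repl_idx], stage = "replication")
  if (length(sig_disc)) {
    gate <- gate_replication(meta_disc[meta_disc$unit_id %in% sig_disc, ],
                             meta_repl, m_repl = nrow(meta_repl))
    replicated <- gate$unit_id[gate$replicated]
  } else {
    gate <- data.frame(unit_id = character(0), replicated = logical(0))
    replicated <- character(0)
  }
  meta_comb <- combine_stages(
    disc_stats[disc_stats$unit_id %in% replicated, , drop = FALSE],
    repl_stats[repl_stats$unit_id %in% replicated, , drop = FALSE],
    cohorts = cohort_ids)

  truth_pos <- genes$gene_id[genes$age_associated_truth]
  fdr <- if (length(replicated))
    mean(!replicated %in% truth_pos) else NA_real_

  # --- mediation ---------------------------------------------------------
  mediation <- NULL
  target_genes <- if (length(replicated)) replicated else truth_pos
  if (run_mediation && !is.null(med_sim$cpgs) && length(target_genes)) {
    cpgs <- med_sim$cpgs
    pairs <- window_assign(cpgs[, c("cpg_id", "chrom", "pos")],
                           genes[genes$gene_id %in% target_genes, ],
                           window_bp = config$cpg_window_bp)
    m1 <- do.call(rbind, lapply(seq_along(cohorts), function(k)
      fit_model1(cohorts[[k]]$methylation[, unique(pairs$cpg_id),
                                          drop = FALSE],
                 cohorts[[k]]$covariates,
                 adjust = c("sex", "fasting", "smoking", "gran", "lymph",
                            "mono", "ery", "plt"),
                 cohort_id = cohort_ids[k])))
    m2 <- do.call(rbind, lapply(seq_along(cohorts), function(k)
      fit_model2(prepped[[k]]$x, cohorts[[k]]$methylation, pairs,
                 cohorts[[k]]$covariates,
                 adjust = c("plate", "rna_quality"),
                 cohort_id = cohort_ids[k])))
    meta1 <- stouffer_meta(m1, cohorts = cohort_ids, stat = "t_stat")
    meta2 <- stouffer_meta(m2, cohorts = cohort_ids, stat = "t_stat")
    z1 <- meta1$z_meta[match(pairs$cpg_id, meta1$unit_id)]
    z2 <- meta2$z_meta[match(paste(pairs$cpg_id, pairs$gene_id, sep = ":"),
                             meta2$unit_id)]
    ok <- is.finite(z1) & is.finite(z2)
    pairs <- pairs[ok, , drop = FALSE]
    z1 <- z1[ok]
    z2 <- z2[ok]
    sob <- cbind(pairs, sobel_test(z1, z2), z1 = z1, z2 = z2)
    sob$mediator_flag <- flag_mediators(sob)
    ann <- cpgs[match(sob$cpg_id, cpgs$cpg_id), ]
    enr_enh <- enrichment_test(ann$chromhmm_class[sob$mediator_flag] ==
                                 "enhancer",
                               ann$chromhmm_class[!sob$mediator_flag] ==
                                 "enhancer")
    enr_isl <- enrichment_test(ann$island_class[sob$mediator_flag] ==
                                 "island",
                               ann$island_class[!sob$mediator_flag] ==
                                 "island")
    mediation <- list(pairs = pairs, sobel = sob,
                      enrichment = list(enhancer = enr_enh,
                                        island = enr_isl))
  }

  # --- prediction --------------------------------------------------------
  if (is.null(lambda)) {
    pieces <- .predictor_pieces(prepped[-1])
    model <- .assemble_model(pieces, seq_along(prepped[-1]))
    cal <- calibrate_lambda(model$b_marginal, model$R, model$n_eff,
                            prepped[[1]]$x[, model$gene_ids, drop = FALSE],
                            prepped[[1]]$age)
    lambda <- cal$lambda
  }
  preds <- loo_predict(prepped, lambda)
  r_by_cohort <- vapply(preds, attr, numeric(1), "r")
  mean_abs_delta <- mean(abs(unlist(lapply(preds, `[[`, "delta"))))

  # --- delta age vs phenotypes ------------------------------------------
  pheno_names <- colnames(cohorts[[1]]$phenotypes)
  pheno_stats <- do.call(rbind, lapply(pheno_names, function(ph)
    do.call(rbind, lapply(seq_along(cohorts), function(k)
      fit_phenotype_model(cohorts[[k]]$phenotypes[[ph]],
                          preds[[k]]$delta, preds[[k]]$age,
                          unit_id = ph, cohort_id = cohort_ids[k])))))
  pheno_meta <- stouffer_meta(pheno_stats, cohorts = cohort_ids,
                              stage = "combined")

  summary <- list(
    n_genes = config$n_genes,
    n_samples = sum(config$n_per_cohort),
    n_discovery_cohorts = length(disc_idx),
    n_replication_cohorts = length(repl_idx),
    n_discovery_significant = length(sig_disc),
    n_replicated = length(replicated),
    replicated_fdr = fdr,
    n_replicated_negative = sum(meta_comb$z_meta < 0),
    n_replicated_positive = sum(meta_comb$z_meta >= 0),
    lambda = lambda,
    loo_r = as.list(r_by_cohort),
    loo_r_min = min(r_by_cohort),
    mean_abs_delta_age = mean_abs_delta,
    n_mediator_flags = if (is.null(mediation)) NA_integer_
      else sum(mediation$sobel$mediator_flag),
    enhancer_or = if (is.null(mediation)) NA_real_
      else mediation$enrichment$enhancer$odds_ratio,
    island_or = if (is.null(mediation)) NA_real_
      else mediation$enrichment$island$odds_ratio,
    phenotype_meta = stats::setNames(as.list(pheno_meta$z_meta),
                                     pheno_meta$unit_id))

  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (co in cohorts) write_cohort_tsv(co, file.path(out_dir, "cohorts"))
    utils::write.table(meta_comb, file.path(out_dir, "meta_combined.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(mediation))
      utils::write.table(mediation$sobel, file.path(out_dir, "sobel.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }

  list(genes = genes, cpgs = med_sim$cpgs,
       meta = list(discovery = meta_disc, replication = meta_repl,
                   combined = meta_comb, gate = gate,
                   significant_discovery = sig_disc,
                   replicated = replicated),
       mediation = mediation,
       prediction = list(lambda = lambda, predictions = preds,
                         r_by_cohort = r_by_cohort),
       phenotypes = list(stats = pheno_stats, meta = pheno_meta),
       summary = summary)
}
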