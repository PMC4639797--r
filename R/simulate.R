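#' Simulation configuration for multi-cohort expression/methylation data
#'
#' Bundles and validates every knob of the synthetic data generator. The
#' defaults describe the study conditions the rest of the package is exercised
#' under: six cohorts of 500 whole-blood samples, 1,000 genes of which 20%
#' have a linear age effect of 0.3 expression-s.d. per s.d. of age (random
#' sign), five CpG sites per gene within a 250 kb window, and a latent
#' per-sample "ageing rate" offset (s.d. 5 years) that drives both the
#' expression age signal and the phenotypes, which is what makes delta-age
#' associations recoverable downstream.
#'
#' @param n_cohorts number of cohorts.
#' @param n_per_cohort samples per cohort; scalar (recycled) or vector of
#'   length `n_cohorts`.
#' @param n_genes number of genes.
#' @param frac_age_genes fraction of genes with a true age effect, in `[0,1]`.
#' @param age_effect_sd magnitude of the true age effect, in expression s.d.
#'   per s.d. of (effective) age.
#' @param frac_mediated fraction of age genes whose effect is partly routed
#'   through a mediating CpG.
#' @param mediation_strength fraction in `[0,1]` of a mediated gene's age
#'   effect carried by methylation.
#' @param n_cpg_per_gene CpG sites simulated per gene.
#' @param cpg_window_bp half-width of the CpG assignment window around each
#'   gene, base pairs.
#' @param noise_sd residual expression noise s.d.
#' @param ageing_rate_sd s.d. (years) of the latent per-sample ageing offset.
#'   The offset is added to the age used to generate expression but not to the
#'   recorded chronological age.
#' @param phenotype_coupling phenotype effect of the latent offset, in
#'   phenotype-s.d. per year of offset.
#' @param age_range numeric length-2, min < max, chronological age in years.
#' @param seed integer seed; all generator functions are deterministic given it.
#' @return A validated list of class `"sim_config"`.
#' @export
sim_config <- function(n_cohorts = 6, n_per_cohort = 500, n_genes = 1000,
                       frac_age_genes = 0.2, age_effect_sd = 0.3,
                       frac_mediated = 0.5, mediation_strength = 0.5,
                       n_cpg_per_gene = 5, cpg_window_bp = 250000,
                       noise_sd = 1, ageing_rate_sd = 5,
                       phenotype_coupling = 0.1, age_range = c(20, 80),
                       seed = 1L) {
  cfg <- list(n_cohorts = n_cohorts, n_per_cohort = n_per_cohort,
              n_genes = n_genes, frac_age_genes = frac_age_genes,
              age_effect_sd = age_effect_sd, frac_mediated = frac_mediated,
              mediation_strength = mediation_strength,
              n_cpg_per_gene = n_cpg_per_gene, cpg_window_bp = cpg_window_bp,
              noise_sd = noise_sd, ageing_rate_sd = ageing_rate_sd,
              phenotype_coupling = phenotype_coupling, age_range = age_range,
              seed = seed)
  .chk_count <- function(x, nm, min = 1) {
    if (!is.numeric(x) || any(!is.finite(x)) || any(x < min) ||
        any(x != round(x)))
      stop("invalid config field '", nm, "': must be integer >= ", min,
           call. = FALSE)
  }
  .chk_frac <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0 || x > 1)
      stop("invalid config field '", nm, "': must be a fraction in [0,1]",
           call. = FALSE)
  }
  .chk_pos <- function(x, nm) {
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < 0)
      stop("invalid config field '", nm, "': must be nonnegative",
           call. = FALSE)
  }
  .chk_count(cfg$n_cohorts, "n_cohorts")
  .chk_count(cfg$n_per_cohort, "n_per_cohort", min = 3)
  if (!length(cfg$n_per_cohort) %in% c(1L, cfg$n_cohorts))
    stop("invalid config field 'n_per_cohort': length must be 1 or n_cohorts",
         call. = FALSE)
  cfg$n_per_cohort <- rep_len(as.integer(cfg$n_per_cohort), cfg$n_cohorts)
  .chk_count(cfg$n_genes, "n_genes")
  .chk_count(cfg$n_cpg_per_gene, "n_cpg_per_gene", min = 0)
  .chk_frac(cfg$frac_age_genes, "frac_age_genes")
  .chk_frac(cfg$frac_mediated, "frac_mediated")
  .chk_frac(cfg$mediation_strength, "mediation_strength")
  .chk_pos(cfg$age_effect_sd, "age_effect_sd")
  .chk_pos(cfg$cpg_window_bp, "cpg_window_bp")
  .chk_pos(cfg$noise_sd, "noise_sd")
  .chk_pos(cfg$ageing_rate_sd, "ageing_rate_sd")
  .chk_pos(abs(cfg$phenotype_coupling), "phenotype_coupling")
  if (!is.numeric(cfg$age_range) || length(cfg$age_range) != 2 ||
      any(!is.finite(cfg$age_range)) || cfg$age_range[1] >= cfg$age_range[2])
    stop("invalid config field 'age_range': need [min, max] with min < max",
         call. = FALSE)
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1 || !is.finite(cfg$seed))
    stop("invalid config field 'seed'", call. = FALSE)
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "sim_config"
  cfg
}

# Correlation between the age-standardized latent and a mediating CpG's
# logit-scale methylation; a site property of the generative model.
.MED_AGE_COR <- 0.6
# Fraction of non-mediating CpGs that still drift with age (age-associated
# methylation is abundant genome-wide even where it does not touch expression).
.NONMED_AGE_FRAC <- 0.3
.NONMED_AGE_COR <- 0.4

#' Standardize effective age under a config
#'
#' Uses the theoretical moments of the uniform age distribution so that the
#' planted per-s.d. effects are exact rather than sample-dependent.
#' @keywords internal
.std_age <- function(age_eff, cfg) {
  mu <- mean(cfg$age_range)
  sdev <- diff(cfg$age_range) / sqrt(12)
  (age_eff - mu) / sdev
}

#' Simulate multi-cohort expression data with known age effects
#'
#' Generates, deterministically under `config$seed`, one expression cohort per
#' configured cohort: a sample-by-gene matrix on a log2-intensity-like scale
#' with a linear effect of standardized *effective* age (chronological age
#' plus the latent ageing offset) for the designated age genes, plus sex,
#' plate-batch and RNA-quality effects and i.i.d. Gaussian noise; detection
#' p-values; and a covariate table. Truth needed to score any downstream
#' discovery (true per-gene effects, the latent offset, the standardized
#' effective age) is carried in each cohort's `truth` element.
#'
#' @param config a [sim_config()].
#' @return list with `cohorts` (list of `cohort_dataset`) and `genes`
#'   (gene annotation data.frame: gene_id, chrom, start, end, length_bp,
#'   mean_expression, age_associated_truth, true_beta).
#' @export
simulate_cohorts <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  G <- config$n_genes
  gene_id <- sprintf("gene%05d", seq_len(G))

  # one synthetic chromosome, windows spaced so they never overlap
  spacing <- 2 * config$cpg_window_bp + 150000
  len <- pmin(pmax(round(stats::rlnorm(G, log(20000), 0.8)), 500), 120000)
  start <- (seq_len(G) - 1) * spacing
  genes <- data.frame(gene_id = gene_id, chrom = "chrS",
                      start = start, end = start + len, length_bp = len,
                      stringsAsFactors = FALSE)

  n_age <- round(config$frac_age_genes * G)
  age_idx <- if (n_age > 0) sort(sample.int(G, n_age)) else integer(0)
  true_beta <- numeric(G)
  if (n_age > 0)
    true_beta[age_idx] <- sample(c(-1, 1), n_age, replace = TRUE) *
      config$age_effect_sd
  genes$mean_expression <- stats::runif(G, 6, 11)
  genes$age_associated_truth <- seq_len(G) %in% age_idx
  genes$true_beta <- true_beta

  # technical/biological nuisance structure, shared gene-wise across cohorts
  sex_fx <- ifelse(stats::runif(G) < 0.3, stats::rnorm(G, 0, 0.3), 0)
  rq_fx <- ifelse(stats::runif(G) < 0.2, stats::rnorm(G, 0, 0.1), 0)

  cohorts <- vector("list", config$n_cohorts)
  for (k in seq_len(config$n_cohorts)) {
    n <- config$n_per_cohort[k]
    cid <- sprintf("cohort%02d", k)
    sid <- sprintf("%s_s%04d", cid, seq_len(n))
    age <- round(stats::runif(n, config$age_range[1], config$age_range[2]), 2)
    offset <- stats::rnorm(n, 0, config$ageing_rate_sd)
    z_age <- .std_age(age + offset, config)

    sex <- stats::rbinom(n, 1, 0.5)
    fasting <- stats::rbinom(n, 1, 0.8)
    smoking <- stats::rbinom(n, 1, 0.25)
    plate <- factor(sprintf("P%d", 1 + (seq_len(n) - 1) %/% ceiling(n / 5)))
    rna_quality <- stats::rnorm(n, 8, 0.5)
    cells <- cbind(gran = stats::rnorm(n, 4.0, 0.8),
                   lymph = stats::rnorm(n, 2.0, 0.5),
                   mono = stats::rnorm(n, 0.5, 0.15),
                   ery = stats::rnorm(n, 4.8, 0.4),
                   plt = stats::rnorm(n, 250, 40))
    plate_fx <- matrix(stats::rnorm(nlevels(plate) * G, 0, 0.15),
                       nlevels(plate), G)

    expr <- outer(z_age, true_beta) +
      outer(sex, sex_fx) +
      outer(rna_quality - 8, rq_fx) +
      plate_fx[as.integer(plate), , drop = FALSE] +
      matrix(stats::rnorm(n * G, 0, config$noise_sd), n, G)
    expr <- sweep(expr, 2, genes$mean_expression, "+")
    dimnames(expr) <- list(sid, gene_id)

    detection_p <- matrix(stats::runif(n * G, 0, 0.04), n, G,
                          dimnames = list(sid, gene_id))

    covariates <- data.frame(sample_id = sid, age = age, sex = sex,
                             fasting = fasting, smoking = smoking,
                             cells, plate = plate, rna_quality = rna_quality,
                             stringsAsFactors = FALSE, row.names = sid)

    stopifnot(all(age >= config$age_range[1] & age <= config$age_range[2]))
    cohorts[[k]] <- structure(
      list(cohort_id = cid, expression = expr, detection_p = detection_p,
           methylation = NULL, covariates = covariates, phenotypes = NULL,
           truth = list(offset = offset, z_age = z_age,
                        gene_effects = data.frame(gene_id = gene_id,
                                                  true_beta = true_beta))),
      class = "cohort_dataset")
  }
  list(cohorts = cohorts, genes = genes)
}

#' Simulate CpG methylation with optional mediation of age effects
#'
#' Positions `n_cpg_per_gene` CpG sites uniformly in each gene's assignment
#' window and fills per-cohort sample-by-CpG beta-value matrices. Methylation
#' is generated on the logit scale and mapped through the inverse logit so
#' beta-values always land in `[0,1]` while keeping the age-linear signal
#' approximately intact. For `frac_mediated` of the age genes one CpG becomes
#' a true mediator: its logit methylation tracks effective age (correlation
#' 0.6) and the gene's expression is rewritten so that `mediation_strength`
#' of its age effect flows through that CpG's methylation, leaving the
#' marginal age effect unchanged. Mediating CpGs are preferentially labelled
#' enhancer/insulator and non-island; a fixed share of non-mediating CpGs is
#' age-associated without touching expression.
#'
#' @param config a [sim_config()].
#' @param cohorts list of `cohort_dataset` from [simulate_cohorts()].
#' @param genes gene annotation from [simulate_cohorts()].
#' @return list with updated `cohorts` (methylation filled, mediated genes'
#'   expression rewritten) and `cpgs` annotation data.frame (cpg_id, chrom,
#'   pos, island_class, chromhmm_class, gene_id, is_mediator,
#'   age_associated_truth).
#' @export
simulate_methylation <- function(config, cohorts, genes) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 1009L)
  if (config$n_cpg_per_gene == 0)
    return(list(cohorts = cohorts, cpgs = NULL))
  G <- nrow(genes)
  ncpg <- config$n_cpg_per_gene
  total <- G * ncpg
  gene_of <- rep(seq_len(G), each = ncpg)
  lo <- pmax(genes$start[gene_of] - config$cpg_window_bp, 0)
  hi <- genes$end[gene_of] + config$cpg_window_bp - 1
  pos <- floor(stats::runif(total, lo, hi + 1))
  cpg_id <- sprintf("cpg%06d", seq_len(total))

  # choose mediators: one CpG (the first simulated) of each mediated age gene
  age_genes <- which(genes$age_associated_truth)
  n_med <- round(config$frac_mediated * length(age_genes))
  med_genes <- if (n_med > 0) sort(sample(age_genes, n_med)) else integer(0)
  is_med <- logical(total)
  is_med[(med_genes - 1) * ncpg + 1] <- TRUE

  # feature labels: mediators preferentially enhancer/insulator and non-island
  isl_lv <- c("island", "shore", "shelf", "open_sea")
  hmm_lv <- c("promoter", "enhancer", "insulator", "other")
  island_class <- ifelse(is_med,
    sample(isl_lv, total, replace = TRUE, prob = c(.10, .20, .20, .50)),
    sample(isl_lv, total, replace = TRUE, prob = c(.40, .25, .15, .20)))
  chromhmm_class <- ifelse(is_med,
    sample(hmm_lv, total, replace = TRUE, prob = c(.05, .60, .15, .20)),
    sample(hmm_lv, total, replace = TRUE, prob = c(.30, .15, .05, .50)))

  age_assoc <- is_med
  pool <- which(!is_med)
  drift <- pool[stats::runif(length(pool)) < .NONMED_AGE_FRAC]
  age_assoc[drift] <- TRUE

  l0 <- stats::runif(total, -1, 1)   # per-site baseline logit, shared
  sig <- 0.8                         # logit-scale spread
  cor_age <- ifelse(is_med, .MED_AGE_COR,
                    ifelse(age_assoc, .NONMED_AGE_COR, 0))

  s <- config$mediation_strength
  for (k in seq_along(cohorts)) {
    co <- cohorts[[k]]
    n <- nrow(co$expression)
    z_age <- co$truth$z_age
    eps <- matrix(stats::rnorm(n * total), n, total)
    zm <- sweep(eps, 2, sqrt(1 - cor_age^2), "*") + outer(z_age, cor_age)
    lgt <- sweep(zm * sig, 2, l0, "+")
    beta <- stats::plogis(lgt)
    dimnames(beta) <- list(rownames(co$expression), cpg_id)
    co$methylation <- beta

    if (n_med > 0 && s > 0) {
      # reroute share s of each mediated gene's age effect through its CpG:
      # e_new = e_old + b*s*(zm/c - z_age); marginal slope on z_age unchanged
      med_cpg <- which(is_med)
      for (j in seq_along(med_genes)) {
        g <- med_genes[j]
        b <- genes$true_beta[g]
        co$expression[, g] <- co$expression[, g] +
          b * s * (zm[, med_cpg[j]] / .MED_AGE_COR - z_age)
      }
    }
    cohorts[[k]] <- co
  }

  cpgs <- data.frame(cpg_id = cpg_id, chrom = "chrS", pos = pos,
                     island_class = island_class,
                     chromhmm_class = chromhmm_class,
                     gene_id = genes$gene_id[gene_of],
                     is_mediator = is_med,
                     age_associated_truth = age_assoc,
                     stringsAsFactors = FALSE)
  list(cohorts = cohorts, cpgs = cpgs)
}

# phenotype panel: intercept, slope on chronological age, residual s.d.,
# sign of the latent-offset coupling
.PHENO_PANEL <- data.frame(
  phenotype = c("sbp", "dbp", "chol", "hdl", "glucose", "bmi"),
  intercept = c(110, 70, 4.2, 1.6, 4.6, 24),
  slope_age = c(0.45, 0.20, 0.020, -0.003, 0.015, 0.05),
  sd = c(12, 8, 0.9, 0.35, 0.7, 3.5),
  coupling_sign = c(1, 1, 1, 1, 1, 1),
  stringsAsFactors = FALSE)

#' Simulate ageing phenotypes coupled to the latent ageing offset
#'
#' Each phenotype is `intercept + slope_age * age + coupling_sign *
#' phenotype_coupling * sd * offset + Normal(0, sd)`, so
#' `phenotype_coupling` is the offset effect in phenotype-s.d. per year of
#' latent offset. With coupling 0 the phenotype is independent of the offset
#' given age.
#'
#' @param config a [sim_config()].
#' @param cohorts list of `cohort_dataset` (offsets already present).
#' @param panel optional phenotype definition data.frame with columns
#'   phenotype, intercept, slope_age, sd, coupling_sign; defaults to a
#'   six-phenotype blood-pressure/lipids/glucose/BMI panel.
#' @return the cohorts, with `phenotypes` tables filled.
#' @export
simulate_phenotypes <- function(config, cohorts, panel = .PHENO_PANEL) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed + 2003L)
  for (k in seq_along(cohorts)) {
    co <- cohorts[[k]]
    n <- nrow(co$covariates)
    age <- co$covariates$age
    off <- co$truth$offset
    ph <- lapply(seq_len(nrow(panel)), function(i) {
      p <- panel[i, ]
      p$intercept + p$slope_age * age +
        p$coupling_sign * config$phenotype_coupling * p$sd * off +
        stats::rnorm(n, 0, p$sd)
    })
    ph <- as.data.frame(ph, col.names = panel$phenotype,
                        row.names = rownames(co$covariates))
    cohorts[[k]]$phenotypes <- ph
  }
  cohorts
}

#' @export
print.cohort_dataset <- function(x, ...) {
  cat("<cohort_dataset> ", x$cohort_id, ": ",
      nrow(x$expression), " samples x ", ncol(x$expression), " genes",
      if (!is.null(x$methylation))
        paste0(", ", ncol(x$methylation), " CpGs"),
      if (!is.null(x$phenotypes))
        paste0(", ", ncol(x$phenotypes), " phenotypes"),
      "\n", sep = "")
  invisible(x)
}
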