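#' Sample-size-weighted (Stouffer) meta-analysis of per-cohort statistics
#'
#' Combines per-cohort z-statistics for each unit as `sum(w_i z_i)` with
#' `w_i = sqrt(n_i) / sqrt(sum n_j)` over the cohorts contributing to that
#' unit, so the squared weights sum to 1. Two-sided p-values come from the
#' normal tail (floored at 1e-300). Cohorts missing a unit contribute `?` to
#' the direction string and are excluded from the weights. Units missing in
#' every cohort are dropped with a warning.
#'
#' @param stats data.frame of per-cohort statistics with columns `unit_id`,
#'   `cohort_id`, `n` and the statistic column named by `stat`.
#' @param cohorts cohort ordering for the direction string; defaults to
#'   order of first appearance.
#' @param stat column to combine; `"z"` for the expression-age models,
#'   `"t_stat"` for the methylation models (weighted sum of t-statistics).
#' @param stage label stored in the output (`discovery`, `replication`,
#'   `combined`).
#' @return data.frame with unit_id, z_meta, p_meta, n_total,
#'   direction_string, stage.
#' @export
stouffer_meta <- function(stats, cohorts = NULL, stat = "z",
                          stage = "discovery") {
  stopifnot(all(c("unit_id", "cohort_id", "n", stat) %in% colnames(stats)))
  if (nrow(stats) == 0)
    return(data.frame(unit_id = character(0), z_meta = numeric(0),
                      p_meta = numeric(0), n_total = numeric(0),
                      direction_string = character(0),
                      stage = character(0), stringsAsFactors = FALSE))
  if (is.null(cohorts)) cohorts <- unique(stats$cohort_id)
  units <- unique(stats$unit_id)
  idx <- cbind(match(stats$unit_id, units), match(stats$cohort_id, cohorts))
  zi <- matrix(NA_real_, length(units), length(cohorts))
  ni <- matrix(NA_real_, length(units), length(cohorts))
  zi[idx] <- stats[[stat]]
  ni[idx] <- stats$n
  present <- !is.na(zi) & !is.na(ni)
  ni[!present] <- NA
  zi[!present] <- NA
  n_tot <- rowSums(ni, na.rm = TRUE)
  w <- sqrt(ni) / sqrt(n_tot)
  z_meta <- rowSums(w * zi, na.rm = TRUE)
  any_present <- rowSums(present) > 0
  if (!all(any_present))
    warning("dropping ", sum(!any_present), " unit(s) missing in all cohorts")
  dir_chr <- matrix("?", nrow(zi), ncol(zi))
  dir_chr[present] <- ifelse(zi[present] >= 0, "+", "-")
  p <- pmin(pmax(2 * stats::pnorm(abs(z_meta), lower.tail = FALSE),
                 1e-300), 1)
  out <- data.frame(unit_id = units, z_meta = z_meta, p_meta = p,
                    n_total = n_tot,
                    direction_string = apply(dir_chr, 1, paste, collapse = ""),
                    stage = stage, stringsAsFactors = FALSE)
  out[any_present, , drop = FALSE]
}

#' Bonferroni significance threshold
#'
#' @param alpha family-wise error rate, in (0,1).
#' @param m number of tests, >= 1.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stop("alpha must be in (0,1)")
  if (!is.numeric(m) || m < 1)
    stop("m must be a positive count")
  thr <- alpha / m
  message("Bonferroni threshold ", format(signif(thr, 3), scientific = TRUE),
          " (", alpha, "/", m, ")")
  thr
}

#' Discovery gate: transcriptome-wide significant units
#'
#' @param meta data.frame from [stouffer_meta()] (discovery stage).
#' @param m number of units tested (computed from the data, not hard-coded).
#' @param alpha family-wise error rate.
#' @return character vector of unit ids with `p_meta` strictly below
#'   `alpha/m`.
#' @export
gate_discovery <- function(meta, m = nrow(meta), alpha = 0.05) {
  if (nrow(meta) == 0) return(character(0))
  thr <- suppressMessages(bonferroni_threshold(alpha, m))
  meta$unit_id[meta$p_meta < thr]
}

#' Replication gate: significance plus direction agreement
#'
#' A unit replicates iff its replication-stage p is strictly below
#' `alpha/m_repl` and the replication z has the same sign as the discovery z.
#' Units missing from either stage are reported not replicated.
#'
#' @param disc,repl data.frames from [stouffer_meta()] for the two stages.
#' @param m_repl number of units carried into replication.
#' @param alpha family-wise error rate.
#' @return data.frame unit_id, z_disc, z_repl, p_repl, replicated.
#' @export
gate_replication <- function(disc, repl, m_repl = nrow(repl), alpha = 0.05) {
  thr <- suppressMessages(bonferroni_threshold(alpha, m_repl))
  i <- match(disc$unit_id, repl$unit_id)
  z_repl <- repl$z_meta[i]
  p_repl <- repl$p_meta[i]
  replicated <- !is.na(z_repl) & p_repl < thr &
    sign(z_repl) == sign(disc$z_meta) & sign(z_repl) != 0
  if (anyNA(z_repl))
    message(sum(is.na(z_repl)), " unit(s) missing from replication stage")
  data.frame(unit_id = disc$unit_id, z_disc = disc$z_meta,
             z_repl = z_repl, p_repl = p_repl, replicated = replicated,
             stringsAsFactors = FALSE)
}

#' Combined meta-analysis over discovery and replication cohorts
#'
#' Stouffer combination over the pooled per-cohort statistics of both stages.
#'
#' @param disc_stats,repl_stats per-cohort statistic data.frames
#'   (as produced by the `fit_*` functions) for the two stages.
#' @param cohorts optional fixed cohort order for the direction string.
#' @param stat statistic column to combine.
#' @return data.frame from [stouffer_meta()] with stage `"combined"`.
#' @export
combine_stages <- function(disc_stats, repl_stats, cohorts = NULL,
                           stat = "z") {
  stouffer_meta(rbind(disc_stats, repl_stats), cohorts = cohorts,
                stat = stat, stage = "combined")
}
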