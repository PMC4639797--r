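#' @title Per-cohort linear association models
#' @description Per-gene / per-CpG least-squares fits with a single focal
#'   predictor, computed by the Frisch–Waugh partial-regression route so that
#'   thousands of units are fitted with two matrix residualizations and one
#'   cross-product. t-statistics are converted to z tail-wise through the
#'   t distribution (sign preserved, log-scale tails so extreme statistics do
#'   not underflow), the METAL-compatible convention.
#' @name association
NULL

#' Convert a t-statistic to a signed z-score tail-wise
#'
#' `z = sign(t) * qnorm(P(T_df > |t|))`, evaluated on the log scale.
#' @param t numeric vector of t-statistics.
#' @param df residual degrees of freedom.
#' @return numeric vector of z-scores.
#' @export
t_to_z <- function(t, df) {
  lp <- stats::pt(abs(t), df, lower.tail = FALSE, log.p = TRUE)
  sign(t) * stats::qnorm(lp, lower.tail = FALSE, log.p = TRUE)
}

.P_FLOOR <- 1e-300
# |z| corresponding to the two-sided p floor; exact fits (zero residual) cap
# here instead of propagating infinities
.Z_CAP <- stats::qnorm(.P_FLOOR / 2, lower.tail = FALSE)

# core: per-column association of Y with focal x, adjusted for Z (no
# intercept needed in Z caller-side; one is always added here)
.partial_assoc <- function(Y, x, adj = NULL) {
  n <- nrow(Y)
  Z <- cbind(`(Intercept)` = rep(1, n), adj)
  qz <- qr(Z)
  if (qz$rank < ncol(Z)) {
    bad <- colnames(Z)[-seq_len(qz$rank)]
    stop("rank-deficient adjustment design; offending columns: ",
         paste(bad, collapse = ", "))
  }
  rx <- qr.resid(qz, x)
  sxx <- sum(rx^2)
  if (sxx < 1e-12)
    stop("focal predictor collinear with adjusters")
  ry <- qr.resid(qz, Y)
  beta <- as.vector(crossprod(ry, rx)) / sxx
  df <- n - qz$rank - 1L
  if (df < 1) stop("not enough samples: n must exceed model parameters")
  rss <- pmax(colSums(ry^2) - beta^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  tt <- beta / se
  sd_y <- apply(Y, 2, stats::sd)
  tt[is.nan(tt) | sd_y < 1e-12] <- NA_real_
  z <- pmin(pmax(t_to_z(tt, df), -.Z_CAP), .Z_CAP)
  p <- pmin(pmax(2 * stats::pnorm(abs(z), lower.tail = FALSE), .P_FLOOR), 1)
  data.frame(unit_id = colnames(Y), beta = beta, se = se, t_stat = tt,
             z = z, p = p, n = n,
             direction = ifelse(is.na(z), "?", ifelse(z >= 0, "+", "-")),
             stringsAsFactors = FALSE, row.names = NULL)
}

# expand a covariate data.frame into a numeric adjuster matrix (treatment
# coding for factors), keeping only the requested columns that exist
.adjuster_matrix <- function(covariates, adjust) {
  adjust <- intersect(adjust, colnames(covariates))
  if (!length(adjust)) return(NULL)
  mm <- stats::model.matrix(~ ., data = covariates[, adjust, drop = FALSE])
  mm[, -1, drop = FALSE]
}

#' Fit the per-gene expression-on-age model for one cohort
#'
#' OLS of (standardized) expression on chronological age plus adjusters;
#' returns one row per gene with the age coefficient's statistics.
#'
#' @param expr sample-by-gene matrix of standardized expression (residuals).
#' @param covariates cohort covariate table; must contain `age`.
#' @param adjust character vector of covariate names to adjust for
#'   (never `age`).
#' @param cohort_id label copied into the output.
#' @return data.frame with columns unit_id, beta, se, t_stat, z, p, n,
#'   direction, cohort_id.
#' @export
fit_age_model <- function(expr, covariates, adjust = character(),
                          cohort_id = "cohort") {
  stopifnot("age" %in% colnames(covariates), nrow(covariates) == nrow(expr))
  out <- .partial_assoc(expr, covariates$age,
                        .adjuster_matrix(covariates, setdiff(adjust, "age")))
  out$cohort_id <- cohort_id
  out
}

#' Model 1: methylation beta-values regressed on chronological age
#'
#' Per CpG, the age coefficient's t/z statistics, adjusted for the
#' methylation-side covariates (sex, fasting, smoking, cell counts, chip/row
#' as available). Constant-beta CpGs are flagged NA rather than fitted.
#'
#' @param meth sample-by-CpG beta-value matrix.
#' @inheritParams fit_age_model
#' @return data.frame as [fit_age_model()], unit_id = cpg_id.
#' @export
fit_model1 <- function(meth, covariates, adjust = character(),
                       cohort_id = "cohort") {
  stopifnot("age" %in% colnames(covariates), nrow(covariates) == nrow(meth))
  out <- .partial_assoc(meth, covariates$age,
                        .adjuster_matrix(covariates, setdiff(adjust, "age")))
  out$cohort_id <- cohort_id
  out
}

#' Model 2: expression regressed on methylation, adjusted for age
#'
#' Per CpG–gene pair, the methylation coefficient's t/z statistics from the
#' regression of the gene's expression on the CpG's beta-values and
#' chronological age plus the expression-side adjusters. Pairs whose CpG is
#' essentially collinear with age (|r| > 0.999) are flagged NA.
#'
#' @param expr sample-by-gene standardized expression matrix.
#' @param meth sample-by-CpG beta-value matrix (same samples).
#' @param pairs data.frame with columns `cpg_id`, `gene_id`.
#' @inheritParams fit_age_model
#' @return data.frame with unit_id = "cpg_id:gene_id" plus cpg_id/gene_id
#'   columns.
#' @export
fit_model2 <- function(expr, meth, pairs, covariates, adjust = character(),
                       cohort_id = "cohort") {
  stopifnot(all(c("cpg_id", "gene_id") %in% colnames(pairs)),
            "age" %in% colnames(covariates))
  n <- nrow(expr)
  adj <- cbind(age = covariates$age,
               .adjuster_matrix(covariates, setdiff(adjust, "age")))
  Z <- cbind(1, adj)
  qz <- qr(Z)
  ucpg <- unique(pairs$cpg_id)
  ugene <- unique(pairs$gene_id)
  rm_ <- qr.resid(qz, meth[, ucpg, drop = FALSE])
  re_ <- qr.resid(qz, expr[, ugene, drop = FALSE])
  i_c <- match(pairs$cpg_id, ucpg)
  i_g <- match(pairs$gene_id, ugene)
  sxx <- colSums(rm_^2)[i_c]
  sxy <- colSums(rm_[, i_c, drop = FALSE] * re_[, i_g, drop = FALSE])
  syy <- colSums(re_^2)[i_g]
  beta <- sxy / sxx
  df <- n - qz$rank - 1L
  rss <- pmax(syy - beta^2 * sxx, 0)
  se <- sqrt(rss / df / sxx)
  tt <- beta / se
  # degenerate / collinear flags
  r_age <- suppressWarnings(stats::cor(meth[, ucpg, drop = FALSE],
                                       covariates$age))[i_c]
  bad <- is.nan(tt) | (is.finite(r_age) & abs(r_age) > 0.999)
  tt[bad] <- NA_real_
  z <- pmin(pmax(t_to_z(tt, df), -.Z_CAP), .Z_CAP)
  p <- pmin(pmax(2 * stats::pnorm(abs(z), lower.tail = FALSE), .P_FLOOR), 1)
  data.frame(unit_id = paste(pairs$cpg_id, pairs$gene_id, sep = ":"),
             cpg_id = pairs$cpg_id, gene_id = pairs$gene_id,
             beta = beta, se = se, t_stat = tt, z = z, p = p, n = n,
             direction = ifelse(is.na(z), "?", ifelse(z >= 0, "+", "-")),
             cohort_id = cohort_id,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Phenotype on delta age, adjusted for chronological age (and optionally BMI)
#'
#' Robust outlier exclusion first: phenotype values with
#' `|value - median| > 4 * MAD` are dropped (count reported as attribute
#' `n_outliers`), then OLS of phenotype on delta age adjusted for age
#' (and BMI when `bmi_adjust`).
#'
#' @param phenotype numeric vector.
#' @param delta_age numeric vector (years), same samples.
#' @param age numeric chronological age vector.
#' @param bmi numeric BMI vector, required when `bmi_adjust`.
#' @param bmi_adjust also adjust for BMI.
#' @param unit_id label for the output row.
#' @param cohort_id label copied into the output.
#' @return one-row data.frame as [fit_age_model()].
#' @export
fit_phenotype_model <- function(phenotype, delta_age, age, bmi = NULL,
                                bmi_adjust = FALSE, unit_id = "phenotype",
                                cohort_id = "cohort") {
  stopifnot(length(phenotype) == length(delta_age),
            length(phenotype) == length(age))
  if (bmi_adjust && is.null(bmi))
    stop("bmi_adjust = TRUE requires bmi")
  med <- stats::median(phenotype, na.rm = TRUE)
  mad_ <- stats::mad(phenotype, na.rm = TRUE)
  keep <- !is.na(phenotype) & !is.na(delta_age) & !is.na(age)
  if (mad_ > 0) keep <- keep & abs(phenotype - med) <= 4 * mad_
  if (bmi_adjust) keep <- keep & !is.na(bmi)
  adj <- if (bmi_adjust) cbind(age = age[keep], bmi = bmi[keep])
         else cbind(age = age[keep])
  out <- .partial_assoc(matrix(phenotype[keep], ncol = 1,
                               dimnames = list(NULL, unit_id)),
                        delta_age[keep], adj)
  out$cohort_id <- cohort_id
  attr(out, "n_outliers") <- sum(!keep)
  out
}
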