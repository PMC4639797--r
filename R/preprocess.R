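#' Quantile-normalize a raw expression matrix to the median distribution
#'
#' Every sample (row) is forced to the reference distribution formed by the
#' across-sample median of each order statistic, then log2-transformed.
#' Within-sample ranks are preserved; tied values receive the mean of the
#' reference values spanned by their tied ranks.
#'
#' @param m numeric sample-by-gene matrix of strictly positive raw
#'   intensities.
#' @return matrix of the same shape on the log2 scale, `scale_tag`
#'   attribute set to `"qnorm_log2"`.
#' @export
quantile_normalize_log2 <- function(m) {
  stopifnot(is.matrix(m), is.numeric(m))
  if (any(m <= 0))
    stop("quantile_normalize_log2: nonpositive values; log2 requires > 0")
  sorted <- t(apply(m, 1, sort))            # n x G, each row sorted
  ref <- apply(sorted, 2, stats::median)    # median distribution
  out <- t(apply(m, 1, function(x) {
    r <- rank(x, ties.method = "average")
    lo <- ref[floor(r)]
    hi <- ref[ceiling(r)]
    (lo + hi) / 2
  }))
  dimnames(out) <- dimnames(m)
  out <- log2(out)
  attr(out, "scale_tag") <- "qnorm_log2"
  out
}

#' Center probe and sample means to zero
#'
#' Alternates row (sample) and column (probe) mean removal until both sets of
#' means are below `tol` in absolute value, up to `max_iter` sweeps.
#'
#' @param m numeric matrix.
#' @param tol convergence tolerance on the largest absolute row/column mean.
#' @param max_iter maximum sweeps.
#' @return centered matrix, `scale_tag` set to `"centered"`.
#' @export
center_matrix <- function(m, tol = 1e-10, max_iter = 100) {
  stopifnot(is.matrix(m), is.numeric(m))
  for (i in seq_len(max_iter)) {
    if (max(abs(rowMeans(m)), abs(colMeans(m))) < tol) break
    m <- sweep(m, 1, rowMeans(m))
    m <- sweep(m, 2, colMeans(m))
  }
  attr(m, "scale_tag") <- "centered"
  m
}

#' Expression filter on detection p-values and cross-cohort presence
#'
#' A gene is kept iff strictly more than `frac` of all discovery samples have
#' detection p below `p_thresh` and the gene was measured in at least
#' `min_cohorts` cohorts.
#'
#' @param detection_p sample-by-gene matrix of detection p-values over all
#'   discovery samples (NA where a gene was not measured for a sample).
#' @param per_cohort_presence list, one character vector of measured gene ids
#'   per cohort.
#' @param p_thresh detection p cutoff.
#' @param frac strict lower bound on the fraction of samples passing.
#' @param min_cohorts minimum number of cohorts in which the gene is measured.
#' @return character vector of retained gene ids.
#' @export
filter_expressed <- function(detection_p, per_cohort_presence,
                             p_thresh = 0.05, frac = 0.10, min_cohorts = 2) {
  stopifnot(is.matrix(detection_p), !is.null(colnames(detection_p)))
  genes <- colnames(detection_p)
  pres <- table(factor(unlist(lapply(per_cohort_presence, unique)),
                       levels = genes))
  n_samp <- nrow(detection_p)
  frac_pass <- colSums(detection_p < p_thresh, na.rm = TRUE) / n_samp
  keep <- frac_pass > frac & as.vector(pres[genes]) >= min_cohorts
  genes[keep]
}

#' Standardized residuals of expression on technical/biological covariates
#'
#' Per gene, OLS residuals of expression on the listed covariates (factors
#' expanded to treatment-coded indicators), divided by their sample s.d.
#' (n-1 denominator). Age must not be in the covariate list: it is the
#' exposure of the association stage, not a nuisance.
#'
#' @param m numeric sample-by-gene matrix.
#' @param covariates data.frame aligned with rows of `m`.
#' @param covariate_list character vector of covariate column names; empty
#'   means plain per-gene standardization.
#' @return matrix of standardized residuals (gene-wise mean 0, s.d. 1),
#'   `scale_tag` set to `"residual_standardized"`. Samples with missing
#'   covariate values are dropped, with a message.
#' @export
residualize <- function(m, covariates, covariate_list = character()) {
  stopifnot(is.matrix(m), nrow(covariates) == nrow(m))
  if ("age" %in% covariate_list)
    stop("residualize: 'age' must not be residualized out")
  if (length(covariate_list)) {
    cv <- covariates[, covariate_list, drop = FALSE]
    ok <- stats::complete.cases(cv)
    if (!all(ok)) {
      message("residualize: dropping ", sum(!ok),
              " samples with missing covariates")
      m <- m[ok, , drop = FALSE]
      cv <- cv[ok, , drop = FALSE]
    }
    X <- stats::model.matrix(~ ., data = cv)
    qx <- qr(X)
    if (qx$rank < ncol(X)) {
      bad <- colnames(X)[-seq_len(qx$rank)]
      stop("residualize: singular covariate design; offending columns: ",
           paste(bad, collapse = ", "))
    }
    res <- qr.resid(qx, m)
  } else {
    res <- sweep(m, 2, colMeans(m))
  }
  sdev <- apply(res, 2, stats::sd)
  if (any(sdev < 1e-12))
    stop("residualize: zero residual s.d. for gene(s): ",
         paste(colnames(m)[sdev < 1e-12], collapse = ", "))
  out <- sweep(res, 2, sdev, "/")
  dimnames(out) <- list(rownames(res), colnames(m))
  attr(out, "scale_tag") <- "residual_standardized"
  out
}
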