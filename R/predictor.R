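#' @title Summary-statistic ridge transcriptomic age predictor
#' @description Builds joint per-gene effects on age from meta-analysis
#'   z-scores and a reference gene-gene correlation matrix, in the spirit of
#'   best linear unbiased prediction from marginal summary statistics:
#'   marginal standardized effects `b = z / sqrt(z^2 + n - 2)` are converted
#'   to joint effects `b_R = ((n-1) R + lambda I)^-1 (n-1) b`, which weight a
#'   new individual's standardized expression profile into a raw predictor
#'   `Z` that is then rescaled to the age scale of a validation cohort.
#' @name age_predictor
NULL

#' Convert a meta-analysis z-score to a standardized marginal effect
#'
#' The standardized-regression identity between a t/z statistic and the
#' correlation-scale slope: `b = z / sqrt(z^2 + n - 2)`, in s.d. of age per
#' s.d. of expression.
#'
#' @param z numeric vector of association z-scores.
#' @param n sample size(s), must exceed 2.
#' @return numeric vector of standardized effects.
#' @export
z_to_beta <- function(z, n) {
  if (any(n <= 2)) stop("z_to_beta: n must exceed 2")
  z / sqrt(z^2 + n - 2)
}

#' Sample-size-weighted reference correlation matrix
#'
#' `R = sum(n_i R_i) / sum(n_i)` over per-cohort sample correlation matrices
#' of the (standardized) expression matrices, with the diagonal reset to
#' exactly 1. Gene sets must be aligned across cohorts.
#'
#' @param expr_list list of sample-by-gene matrices (identical columns).
#' @return gene-by-gene correlation matrix.
#' @export
reference_correlation <- function(expr_list) {
  stopifnot(length(expr_list) >= 1)
  g0 <- colnames(expr_list[[1]])
  for (m in expr_list)
    if (!identical(colnames(m), g0))
      stop("reference_correlation: gene sets misaligned across cohorts")
  ns <- vapply(expr_list, nrow, numeric(1))
  R <- Reduce(`+`, Map(function(m, n) n * stats::cor(m), expr_list, ns)) /
    sum(ns)
  diag(R) <- 1
  R
}

#' Joint ridge effects from marginal effects and a reference correlation
#'
#' Solves `((n-1) R + lambda I) b_R = (n-1) b` by a symmetric
#' positive-definite (Cholesky) solve; the system matrix is never inverted
#' explicitly. At `lambda = 0` a rank-deficient `R` is reported with the
#' suggestion to use `lambda > 0`.
#'
#' @param b_marginal numeric vector of marginal standardized effects.
#' @param R reference correlation matrix.
#' @param n effective sample size behind `R` (`X'X` is approximated by
#'   `(n-1) R` for standardized probes).
#' @param lambda ridge penalty, >= 0.
#' @return numeric vector `b_R`, named as `b_marginal`.
#' @export
ridge_joint_effects <- function(b_marginal, R, n, lambda) {
  stopifnot(length(b_marginal) == nrow(R), n > 1, lambda >= 0)
  A <- (n - 1) * R
  diag(A) <- diag(A) + lambda
  ch <- tryCatch(chol(A), error = function(e)
    stop("ridge system not positive definite",
         if (lambda == 0) " at lambda = 0; use lambda > 0", call. = FALSE))
  out <- backsolve(ch, forwardsolve(t(ch), (n - 1) * b_marginal))
  names(out) <- names(b_marginal)
  as.vector(out)
}

#' Calibrate the ridge penalty on a held-out cohort
#'
#' For each lambda in the grid, computes joint effects, scores the
#' calibration cohort and records the Pearson correlation between predictor
#' and chronological age; returns the argmax (smallest lambda on ties).
#' The calibration cohort must be excluded from the meta-analysis and from
#' the reference correlation.
#'
#' @param b_marginal,R,n as in [ridge_joint_effects()].
#' @param x_val sample-by-gene standardized expression of the calibration
#'   cohort (columns aligned with `b_marginal`).
#' @param age_val chronological ages of the calibration cohort.
#' @param grid lambda grid; default 25 log-spaced points on `[1, 1e6]`.
#' @return list with `lambda`, `accuracy` (data.frame lambda, r).
#' @export
calibrate_lambda <- function(b_marginal, R, n, x_val, age_val,
                             grid = 10^seq(0, 6, length.out = 25)) {
  if (!length(grid)) stop("calibrate_lambda: empty grid")
  grid <- sort(grid)
  r <- vapply(grid, function(l) {
    z <- as.vector(x_val %*% ridge_joint_effects(b_marginal, R, n, l))
    if (stats::sd(z) == 0) -Inf else stats::cor(z, age_val)
  }, numeric(1))
  list(lambda = grid[which.max(r)], accuracy = data.frame(lambda = grid, r = r))
}

#' Rescale a raw predictor to the age scale
#'
#' `sz = (z - mean(z)) / sd(z) * sigma_age + mu_age`; afterwards
#' `mean(sz) == mu_age` and `sd(sz) == sigma_age` up to floating point.
#'
#' @param z_raw numeric raw predictor values.
#' @param mu_age,sigma_age target mean and s.d. (years).
#' @return numeric vector `sz`, with attributes `mu_z`, `sigma_z`.
#' @export
scale_predictions <- function(z_raw, mu_age, sigma_age) {
  mu_z <- mean(z_raw)
  sigma_z <- stats::sd(z_raw)
  if (!is.finite(sigma_z) || sigma_z == 0)
    stop("scale_predictions: zero predictor variance")
  sz <- (z_raw - mu_z) / sigma_z * sigma_age + mu_age
  attr(sz, "mu_z") <- mu_z
  attr(sz, "sigma_z") <- sigma_z
  sz
}

#' Delta age
#'
#' Scaled transcriptomic age minus chronological age, per individual.
#' @param sz scaled transcriptomic age (years).
#' @param age chronological age (years).
#' @return numeric vector of the same length.
#' @export
delta_age <- function(sz, age) {
  stopifnot(length(sz) == length(age))
  as.vector(sz) - age
}

#' Pooled age mean and s.d. across cohorts from summary moments
#'
#' `mu = sum(n_i mu_i) / sum(n_i)`; the pooled variance combines the
#' within-cohort and between-cohort components:
#' `sigma^2 = (sum((n_i-1) s_i^2) + sum(n_i (mu_i - mu)^2)) / (sum(n_i) - 1)`,
#' which reproduces the moments of the concatenated raw samples.
#'
#' @param cohort_means,cohort_sds,cohort_ns aligned numeric vectors;
#'   at least two cohorts, all `n >= 2`.
#' @return list with `mu` and `sigma`.
#' @export
pooled_age_sd <- function(cohort_means, cohort_sds, cohort_ns) {
  stopifnot(length(cohort_means) >= 2,
            length(cohort_sds) == length(cohort_means),
            length(cohort_ns) == length(cohort_means))
  if (any(cohort_ns < 2)) stop("pooled_age_sd: all cohort n must be >= 2")
  n <- sum(cohort_ns)
  mu <- sum(cohort_ns * cohort_means) / n
  v <- (sum((cohort_ns - 1) * cohort_sds^2) +
          sum(cohort_ns * (cohort_means - mu)^2)) / (n - 1)
  list(mu = mu, sigma = sqrt(v))
}

# ---- model assembly over prepared cohorts -------------------------------

#' Prepare a cohort for prediction: standardized residual expression + age
#'
#' @param cohort a `cohort_dataset`.
#' @param adjust covariate names to residualize out (technical + biological
#'   nuisance; never age).
#' @return list with `x` (standardized residuals), `age`, `n`, `cohort_id`.
#' @export
prepare_cohort <- function(cohort,
                           adjust = c("sex", "fasting", "smoking", "gran",
                                      "lymph", "mono", "ery", "plt", "plate",
                                      "rna_quality")) {
  x <- residualize(cohort$expression, cohort$covariates,
                   intersect(adjust, colnames(cohort$covariates)))
  list(x = x, age = cohort$covariates$age, n = nrow(x),
       cohort_id = cohort$cohort_id)
}

# per-cohort ingredients reused across leave-one-out folds
.predictor_pieces <- function(prepped, adjust_assoc = character()) {
  stats_l <- lapply(prepped, function(p) {
    cov <- data.frame(age = p$age)
    fit_age_model(p$x, cov, adjust = character(), cohort_id = p$cohort_id)
  })
  cors <- lapply(prepped, function(p) stats::cor(p$x))
  ns <- vapply(prepped, `[[`, numeric(1), "n")
  list(stats = stats_l, cors = cors, ns = ns)
}

# meta-analyze the training cohorts and assemble b_marginal, R, n_eff
.assemble_model <- function(pieces, include) {
  stats <- do.call(rbind, pieces$stats[include])
  meta <- stouffer_meta(stats, stage = "discovery")
  ns <- pieces$ns[include]
  R <- Reduce(`+`, Map(`*`, pieces$cors[include], ns)) / sum(ns)
  diag(R) <- 1
  b <- z_to_beta(meta$z_meta, meta$n_total)
  names(b) <- meta$unit_id
  n_eff <- sum(ns^2) / sum(ns)   # sample-size-weighted mean cohort size
  list(gene_ids = meta$unit_id, b_marginal = b, R = R,
       n_eff = n_eff, n_total = sum(ns))
}

#' Leave-one-cohort-out transcriptomic age prediction
#'
#' For each cohort in turn: re-runs the expression-age meta-analysis and the
#' reference correlation on the remaining cohorts only (the validation cohort
#' is completely independent of training), converts meta z-scores to marginal
#' effects, solves the summary-statistic ridge, scores the left-out cohort's
#' individuals, and rescales the raw predictor with the left-out cohort's own
#' age mean/s.d.
#'
#' @param prepped list of prepared cohorts from [prepare_cohort()].
#' @param lambda ridge penalty (e.g. from [calibrate_lambda()]).
#' @param min_overlap abort a fold if the fraction of model genes present in
#'   the validation cohort falls below this floor.
#' @return list per cohort: data.frame with sample_id, z_raw, sz, delta, age
#'   and attributes mu_age, sigma_age, mu_z, sigma_z, r (Pearson r(sz, age)).
#' @export
loo_predict <- function(prepped, lambda, min_overlap = 0.9) {
  stopifnot(length(prepped) >= 2)
  pieces <- .predictor_pieces(prepped)
  out <- vector("list", length(prepped))
  names(out) <- vapply(prepped, `[[`, character(1), "cohort_id")
  for (j in seq_along(prepped)) {
    model <- .assemble_model(pieces, setdiff(seq_along(prepped), j))
    out[[j]] <- predict_cohort(model, prepped[[j]], lambda,
                               min_overlap = min_overlap)
  }
  out
}

#' Score one cohort with an assembled summary-statistic model
#'
#' @param model list with `gene_ids`, `b_marginal`, `R`, `n_eff` (from the
#'   internal assembly or [export_general_predictor()]'s in-memory form).
#' @param prepped_target prepared validation cohort ([prepare_cohort()]).
#' @param lambda ridge penalty.
#' @param min_overlap minimum fraction of model genes present in the target.
#' @return data.frame with sample_id, z_raw, sz, delta, age; scaling
#'   constants and `r` attached as attributes.
#' @export
predict_cohort <- function(model, prepped_target, lambda, min_overlap = 0.9) {
  common <- intersect(model$gene_ids, colnames(prepped_target$x))
  if (length(common) < min_overlap * length(model$gene_ids))
    stop("gene overlap ", length(common), "/", length(model$gene_ids),
         " below floor ", min_overlap)
  keep <- match(common, model$gene_ids)
  b_R <- ridge_joint_effects(model$b_marginal[keep],
                             model$R[keep, keep, drop = FALSE],
                             model$n_eff, lambda)
  z_raw <- as.vector(prepped_target$x[, common, drop = FALSE] %*% b_R)
  age <- prepped_target$age
  sz <- scale_predictions(z_raw, mean(age), stats::sd(age))
  res <- data.frame(sample_id = rownames(prepped_target$x),
                    z_raw = z_raw, sz = as.vector(sz),
                    delta = delta_age(sz, age), age = age,
                    stringsAsFactors = FALSE)
  attr(res, "mu_age") <- mean(age)
  attr(res, "sigma_age") <- stats::sd(age)
  attr(res, "mu_z") <- attr(sz, "mu_z")
  attr(res, "sigma_z") <- attr(sz, "sigma_z")
  attr(res, "lambda") <- lambda
  attr(res, "r") <- stats::cor(res$sz, age)
  res
}

#' Export a general (portable) transcriptomic age predictor
#'
#' Assembles the model from every cohort except the calibration cohort,
#' solves the ridge at the calibrated lambda, and writes a TSV of
#' `gene_id<TAB>weight` preceded by a `#`-prefixed constants block
#' (mu_age, sigma_age, mu_z, sigma_z, lambda, n_eff). The age scale constants
#' are the pooled mean/s.d. of chronological age over the training cohorts;
#' mu_z/sigma_z are the moments of the predictor over the pooled training
#' samples, so a cohort without age data can still be scored in years.
#'
#' @param prepped list of prepared cohorts.
#' @param lambda calibrated ridge penalty.
#' @param calibration_cohort cohort_id to exclude (the lambda donor);
#'   NULL to use all cohorts.
#' @param path optional file path; when given, the predictor file is written.
#' @return invisible list: gene_ids, weights, mu_age, sigma_age, mu_z,
#'   sigma_z, lambda, n_eff.
#' @export
export_general_predictor <- function(prepped, lambda,
                                     calibration_cohort = NULL, path = NULL) {
  ids <- vapply(prepped, `[[`, character(1), "cohort_id")
  include <- which(!ids %in% calibration_cohort)
  if (!length(include)) stop("no cohorts left after exclusion")
  pieces <- .predictor_pieces(prepped[include])
  model <- .assemble_model(pieces, seq_along(include))
  b_R <- ridge_joint_effects(model$b_marginal, model$R, model$n_eff, lambda)
  z_pool <- unlist(lapply(prepped[include], function(p)
    as.vector(p$x[, model$gene_ids, drop = FALSE] %*% b_R)))
  ages <- lapply(prepped[include], `[[`, "age")
  pooled <- if (length(include) >= 2)
    pooled_age_sd(vapply(ages, mean, 1), vapply(ages, stats::sd, 1),
                  lengths(ages))
  else list(mu = mean(ages[[1]]), sigma = stats::sd(ages[[1]]))
  pred <- list(gene_ids = model$gene_ids, weights = b_R,
               mu_age = pooled$mu, sigma_age = pooled$sigma,
               mu_z = mean(z_pool), sigma_z = stats::sd(z_pool),
               lambda = lambda, n_eff = model$n_eff)
  if (!is.null(path)) write_predictor(pred, path)
  invisible(pred)
}

#' Write a predictor file
#' @param pred predictor list as from [export_general_predictor()].
#' @param path output TSV path.
#' @export
write_predictor <- function(pred, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (k in c("mu_age", "sigma_age", "mu_z", "sigma_z", "lambda", "n_eff"))
    writeLines(sprintf("# %s: %.17g", k, pred[[k]]), con)
  writeLines("gene_id\tweight", con)
  writeLines(sprintf("%s\t%.17g", pred$gene_ids, pred$weights), con)
  invisible(path)
}

#' Read a predictor file written by [write_predictor()]
#' @param path predictor TSV path.
#' @return predictor list.
#' @export
read_predictor <- function(path) {
  lines <- readLines(path)
  hdr <- grep("^# ", lines, value = TRUE)
  kv <- regmatches(hdr, regexec("^# ([a-z_]+): (.*)$", hdr))
  consts <- stats::setNames(lapply(kv, function(x) as.numeric(x[3])),
                            vapply(kv, `[`, character(1), 2))
  body <- utils::read.delim(text = lines[!startsWith(lines, "#")],
                            stringsAsFactors = FALSE)
  c(list(gene_ids = body$gene_id,
         weights = stats::setNames(body$weight, body$gene_id)),
    consts)
}

#' Score an external expression matrix with a portable predictor
#'
#' Raw predictor `Z = X[, genes] %*% weights` over the genes present (missing
#' genes are dropped; weights are absolute and not renormalized), then scaled
#' with the stored constants:
#' `sz = (Z - mu_z) / sigma_z * sigma_age + mu_age`.
#'
#' @param pred predictor list from [export_general_predictor()] /
#'   [read_predictor()].
#' @param expr sample-by-gene standardized expression matrix.
#' @param min_overlap minimum fraction of predictor genes present.
#' @return data.frame sample_id, z_raw, sz.
#' @export
predict_external <- function(pred, expr, min_overlap = 0.9) {
  common <- intersect(pred$gene_ids, colnames(expr))
  if (length(common) < min_overlap * length(pred$gene_ids))
    stop("gene overlap below floor")
  z <- as.vector(expr[, common, drop = FALSE] %*%
                   pred$weights[match(common, pred$gene_ids)])
  sz <- (z - pred$mu_z) / pred$sigma_z * pred$sigma_age + pred$mu_age
  data.frame(sample_id = if (is.null(rownames(expr)))
               seq_len(nrow(expr)) else rownames(expr),
             z_raw = z, sz = sz, stringsAsFactors = FALSE)
}
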