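test_that("z-to-effect transformation inverts the standardized regression identity", {
  expect_equal(z_to_beta(0, 100), 0)
  # fixed z, growing n: effect shrinks monotonically to zero
  b <- z_to_beta(3, c(10, 100, 1000, 1e6))
  expect_true(all(diff(b) < 0))
  expect_lt(b[4], 0.01)
  expect_error(z_to_beta(1, 2), "n must exceed 2")
  # round trip: construct data with exact r = 0.196, n = 102
  n <- 102; r <- 0.196
  set.seed(40)
  x <- as.vector(scale(rnorm(n)))
  e <- as.vector(scale(resid(lm(rnorm(n) ~ x))))
  y <- r * x + sqrt(1 - r^2) * e
  t_stat <- unname(summary(lm(y ~ x))$coefficients["x", "t value"])
  expect_equal(z_to_beta(t_stat, n), r, tolerance = 1e-10)
})

test_that("reference correlation is the sample-size-weighted average with unit diagonal", {
  set.seed(41)
  x1 <- matrix(rnorm(200 * 5), 200, 5, dimnames = list(NULL, paste0("g", 1:5)))
  x2 <- matrix(rnorm(100 * 5), 100, 5, dimnames = list(NULL, paste0("g", 1:5)))
  R <- reference_correlation(list(x1, x2))
  expect_equal(R, (200 * cor(x1) + 100 * cor(x2)) / 300, tolerance = 1e-12)
  expect_equal(diag(R), setNames(rep(1, 5), paste0("g", 1:5)))
  expect_equal(reference_correlation(list(x1)), cor(x1), tolerance = 1e-12)
  expect_equal(reference_correlation(list(x1, x1)), cor(x1), tolerance = 1e-12)
  colnames(x2) <- paste0("h", 1:5)
  expect_error(reference_correlation(list(x1, x2)), "misaligned")
})

test_that("ridge limits behave: identity at R=I,lambda=0; shrinkage to zero; monotone norm", {
  b <- c(a = 0.3, b = -0.2, c = 0.1)
  I3 <- diag(3)
  expect_equal(ridge_joint_effects(b, I3, n = 100, lambda = 0), unname(b))
  expect_lt(max(abs(ridge_joint_effects(b, I3, n = 100, lambda = 1e12))),
            1e-8)
  set.seed(42)
  x <- matrix(rnorm(500 * 10), 500, 10)
  R <- cor(x)
  bm <- rnorm(10, 0, 0.1)
  norms <- vapply(c(0, 1, 10, 100, 1e4),
                  function(l) sqrt(sum(ridge_joint_effects(bm, R, 100, l)^2)),
                  numeric(1))
  expect_true(all(diff(norms) < 0))
  # rank-deficient R at lambda = 0 is reported
  R1 <- matrix(1, 3, 3)
  expect_error(ridge_joint_effects(b, R1, 100, 0), "lambda > 0")
})

test_that("summary-statistic ridge equals explicit individual-level ridge", {
  set.seed(43)
  n <- 300; p <- 100
  X <- apply(matrix(rnorm(n * p), n, p), 2, function(v)
    (v - mean(v)) / sd(v))
  colnames(X) <- paste0("g", seq_len(p))
  y <- as.vector(scale(X[, 1:20] %*% rnorm(20, 0, 0.2) + rnorm(n)))
  lambda <- 50
  b_marg <- as.vector(crossprod(X, y)) / (n - 1)   # marginal std effects
  R <- cor(X)
  b_sum <- ridge_joint_effects(b_marg, R, n, lambda)
  b_ind <- solve(crossprod(X) + lambda * diag(p), crossprod(X, y))
  # X'X = (n-1) R for standardized columns, X'y = (n-1) b_marg
  expect_lt(max(abs(b_sum - as.vector(b_ind))), 1e-8)
})

test_that("lambda calibration returns the grid argmax with smallest-lambda ties", {
  set.seed(44)
  p <- 20; n <- 150
  X <- apply(matrix(rnorm(n * p), n, p), 2, scale)
  colnames(X) <- paste0("g", seq_len(p))
  age <- runif(n, 20, 80)
  b <- rnorm(p, 0, 0.1)
  expect_equal(calibrate_lambda(b, diag(p), n, X, age,
                                grid = 42)$lambda, 42)
  # fully degenerate predictor: accuracy identical at every grid point,
  # so the tie rule returns the smallest lambda
  cal <- calibrate_lambda(rep(0, p), diag(p), n, X, age,
                          grid = c(1, 10, 100))
  expect_equal(cal$lambda, 1)
  expect_error(calibrate_lambda(b, diag(p), n, X, age, grid = numeric(0)),
               "empty grid")
})

test_that("prediction scaling hits the target moments exactly and is affine-invariant", {
  set.seed(45)
  z <- rnorm(80)
  sz <- scale_predictions(z, mu_age = 55.3, sigma_age = 11.7)
  expect_equal(mean(sz), 55.3, tolerance = 1e-12)
  expect_equal(sd(sz), 11.7, tolerance = 1e-12)
  sz2 <- scale_predictions(3 * z - 7, 55.3, 11.7)
  expect_equal(as.vector(sz2), as.vector(sz), tolerance = 1e-10)
  expect_error(scale_predictions(rep(1, 10), 50, 10), "zero predictor")
  expect_equal(delta_age(sz, rep(55.3, 80)), as.vector(sz) - 55.3)
})

test_that("pooled age moments equal the moments of the concatenated samples", {
  set.seed(46)
  groups <- list(rnorm(40, 50, 8), rnorm(90, 62, 10), rnorm(25, 45, 5))
  pooled <- pooled_age_sd(vapply(groups, mean, 1),
                          vapply(groups, sd, 1),
                          lengths(groups))
  all_x <- unlist(groups)
  expect_equal(pooled$mu, mean(all_x), tolerance = 1e-10)
  expect_equal(pooled$sigma, sd(all_x), tolerance = 1e-10)
  # between-cohort spread inflates the pooled s.d.
  p2 <- pooled_age_sd(c(40, 60), c(5, 5), c(50, 50))
  expect_gt(p2$sigma, 5)
  expect_error(pooled_age_sd(c(40, 60), c(5, 5), c(1, 50)), ">= 2")
})

test_that("leave-one-out prediction recovers age and degenerate models fail cleanly", {
  cfg <- sim_config(n_cohorts = 3, n_per_cohort = 200, n_genes = 150,
                    frac_age_genes = 0.25, n_cpg_per_gene = 0, seed = 47)
  sim <- simulate_cohorts(cfg)
  prepped <- lapply(sim$cohorts, prepare_cohort)
  preds <- loo_predict(prepped, lambda = 100)
  for (p in preds) {
    expect_gt(attr(p, "r"), 0.5)
    expect_equal(mean(p$sz), mean(p$age), tolerance = 1e-10)
    expect_equal(p$delta, p$sz - p$age)
  }
  # all-zero effects: raw predictor is constant, scaling error surfaces
  model <- list(gene_ids = colnames(prepped[[1]]$x),
                b_marginal = rep(0, 150), R = diag(150), n_eff = 200)
  expect_error(predict_cohort(model, prepped[[1]], lambda = 10),
               "zero predictor")
  # gene overlap floor
  model2 <- list(gene_ids = c(colnames(prepped[[1]]$x), paste0("x", 1:100)),
                 b_marginal = rep(0.1, 250), R = diag(250), n_eff = 200)
  expect_error(predict_cohort(model2, prepped[[1]], lambda = 10),
               "overlap")
})

test_that("prediction is invariant to gene ordering", {
  cfg <- sim_config(n_cohorts = 2, n_per_cohort = 150, n_genes = 60,
                    frac_age_genes = 0.3, n_cpg_per_gene = 0, seed = 48)
  sim <- simulate_cohorts(cfg)
  prepped <- lapply(sim$cohorts, prepare_cohort)
  p1 <- loo_predict(prepped, lambda = 50)
  perm <- sample(60)
  prepped2 <- lapply(prepped, function(p) {
    p$x <- p$x[, perm, drop = FALSE]
    p
  })
  p2 <- loo_predict(prepped2, lambda = 50)
  expect_equal(p1[[1]]$sz, p2[[1]]$sz, tolerance = 1e-8)
})

test_that("exported general predictor round-trips and scores external cohorts", {
  cfg <- sim_config(n_cohorts = 4, n_per_cohort = 200, n_genes = 120,
                    frac_age_genes = 0.25, n_cpg_per_gene = 0, seed = 49)
  sim <- simulate_cohorts(cfg)
  prepped <- lapply(sim$cohorts, prepare_cohort)
  path <- tempfile(fileext = ".tsv")
  on.exit(unlink(path), add = TRUE)
  pred <- export_general_predictor(prepped[1:3], lambda = 100,
                                   calibration_cohort = NULL, path = path)
  expect_equal(length(pred$weights), length(pred$gene_ids))
  back <- read_predictor(path)
  s1 <- predict_external(pred, prepped[[4]]$x)
  s2 <- predict_external(back, prepped[[4]]$x)
  expect_equal(s1$sz, s2$sz, tolerance = 1e-10)
  # external cohort from the same generative process: age recovered
  expect_gt(cor(s1$sz, prepped[[4]]$age), 0.5)
  # calibration cohort is excluded from training
  pred2 <- export_general_predictor(prepped, lambda = 100,
                                    calibration_cohort = "cohort01")
  expect_equal(pred2$n_eff, 200)
  expect_error(export_general_predictor(prepped[1], lambda = 100,
                                        calibration_cohort = "cohort01"),
               "no cohorts")
})

test_that("a null generator yields no cross-cohort age signal", {
  rs <- vapply(1:5, function(s) {
    cfg <- sim_config(n_cohorts = 2, n_per_cohort = 150, n_genes = 80,
                      frac_age_genes = 0, n_cpg_per_gene = 0, seed = 100 + s)
    sim <- simulate_cohorts(cfg)
    prepped <- lapply(sim$cohorts, prepare_cohort)
    attr(loo_predict(prepped, lambda = 100)[[1]], "r")
  }, numeric(1))
  expect_lt(abs(mean(rs)), 0.25)
})
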