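test_that("Sobel statistic reproduces hand-computed values and edge cases", {
  expect_equal(sobel_test(3, 4)$z_sobel, 12 / 5)
  expect_equal(sobel_test(0, 100)$z_sobel, 0)
  expect_equal(sobel_test(0, 0)$z_sobel, 0)
  z <- 2.5
  expect_equal(sobel_test(z, z)$z_sobel, z / sqrt(2))
  expect_equal(sobel_test(-3, 4)$z_sobel, -12 / 5)
})

test_that("|z_sobel| is bounded by min(|z1|, |z2|)", {
  set.seed(30)
  z1 <- rnorm(5000, sd = 3)
  z2 <- rnorm(5000, sd = 3)
  s <- sobel_test(z1, z2)$z_sobel
  expect_true(all(abs(s) <= pmin(abs(z1), abs(z2)) + 1e-12))
})

test_that("mediator flags apply the per-gene Bonferroni rule", {
  sob <- data.frame(gene_id = c("g1", rep("g2", 10)),
                    p_sobel = c(0.04, rep(0.04, 10)))
  fl <- flag_mediators(sob, alpha = 0.05)
  expect_true(fl[1])            # one CpG: threshold 0.05
  expect_false(any(fl[-1]))     # ten CpGs: threshold 0.005
})

test_that("Sobel null flags are conservative at nominal alpha", {
  set.seed(31)
  n_pairs <- 10000
  s <- sobel_test(rnorm(n_pairs), rnorm(n_pairs))
  expect_lte(mean(s$p_sobel < 0.05), 0.05)
})

test_that("window assignment matches an exhaustive double loop and honours boundaries", {
  genes <- data.frame(gene_id = c("g1", "g2", "g3"), chrom = "chr1",
                      start = c(1e6, 2e6, 5e6), end = c(1.02e6, 2.3e6, 5.1e6))
  w <- 250000
  cpgs <- data.frame(
    cpg_id = c("lo_edge", "hi_edge", "inside", "far", "between"),
    chrom = "chr1",
    pos = c(1e6 - w,                # start - window: included (closed)
            1.02e6 + w,             # end + window: excluded (half-open)
            2.1e6, 9e6, 1.9e6))
  pairs <- window_assign(cpgs, genes, w)
  brute <- do.call(rbind, lapply(seq_len(nrow(cpgs)), function(i)
    do.call(rbind, lapply(seq_len(nrow(genes)), function(j) {
      if (cpgs$pos[i] >= genes$start[j] - w &&
          cpgs$pos[i] < genes$end[j] + w)
        data.frame(cpg_id = cpgs$cpg_id[i], gene_id = genes$gene_id[j])
    }))))
  key <- function(d) sort(paste(d$cpg_id, d$gene_id))
  expect_identical(key(pairs), key(brute))
  expect_true("lo_edge" %in% pairs$cpg_id)
  expect_false("hi_edge" %in% pairs$cpg_id)
  expect_error(window_assign(cpgs, genes, -1), "nonnegative")
})

test_that("CpG region classification agrees with brute-force distances", {
  islands <- data.frame(start = c(1000, 10000), end = c(2000, 12000))
  expect_identical(classify_cpg_region(1500, islands), "island")
  expect_identical(classify_cpg_region(2000 + 1500, islands), "shore")
  expect_identical(classify_cpg_region(2000 + 1501, islands), "shelf")
  expect_identical(classify_cpg_region(1000 - 1500, islands), "shore")
  expect_identical(classify_cpg_region(6000, islands), "open_sea")
  set.seed(32)
  pos <- sample(0:20000, 50)
  brute <- vapply(pos, function(p) {
    if (any(p >= islands$start & p < islands$end)) return("island")
    d <- min(pmax(islands$start - p, p - islands$end))  # gap to nearest edge
    if (d <= 1500) "shore" else if (d <= 3000) "shelf" else "open_sea"
  }, character(1))
  expect_identical(classify_cpg_region(pos, islands), brute)
  expect_error(classify_cpg_region(5, data.frame(start = c(10, 1),
                                                 end = c(20, 5))), "sorted")
})

test_that("matched control genes balance length and expression", {
  set.seed(33)
  # targets drawn from a shifted distribution vs a larger candidate pool
  targets <- data.frame(gene_id = paste0("t", 1:100),
                        length_bp = round(rlnorm(100, 10.5, 0.5)),
                        mean_expression = exp(rnorm(100, 2.2, 0.3)))
  candidates <- data.frame(gene_id = paste0("c", 1:500),
                           length_bp = round(rlnorm(500, 10, 0.6)),
                           mean_expression = exp(rnorm(500, 2, 0.4)))
  imbalance <- function(ids) {
    ctl <- candidates[match(ids, candidates$gene_id), ]
    abs(mean(log(ctl$length_bp)) - mean(log(targets$length_bp))) +
      abs(mean(log(ctl$mean_expression)) -
            mean(log(targets$mean_expression)))
  }
  reduction <- replicate(20, {
    matched <- select_matched_random_genes(candidates, targets)
    random <- sample(candidates$gene_id, 100)
    1 - imbalance(matched) / imbalance(random)
  })
  expect_gte(mean(reduction), 0.8)
  ctl <- candidates[match(select_matched_random_genes(candidates, targets),
                          candidates$gene_id), ]
  expect_gt(suppressWarnings(
    ks.test(log(ctl$length_bp), log(targets$length_bp))$p.value), 0.01)
  expect_gt(suppressWarnings(
    ks.test(log(ctl$mean_expression),
            log(targets$mean_expression))$p.value), 0.01)
})

test_that("self-matching is exact and k = 0 returns an empty set", {
  genes <- data.frame(gene_id = paste0("g", 1:20),
                      length_bp = round(runif(20, 1e3, 1e5)),
                      mean_expression = runif(20, 5, 12))
  expect_identical(sort(select_matched_random_genes(genes, genes)),
                   sort(genes$gene_id))
  expect_identical(select_matched_random_genes(genes, genes, k = 0),
                   character(0))
  expect_error(select_matched_random_genes(genes[1:3, ], genes), "pool")
})

test_that("Fisher enrichment reproduces arithmetic ORs and the hypergeometric p", {
  flat <- enrichment_test(rep(c(TRUE, FALSE), each = 10),
                          rep(c(TRUE, FALSE), each = 10))
  expect_equal(flat$odds_ratio, 1)
  strong <- enrichment_test(rep(c(TRUE, FALSE), c(20, 10)),
                            rep(c(TRUE, FALSE), c(10, 20)))
  expect_equal(strong$odds_ratio, 4)
  # independent oracle: enumerate the hypergeometric tail for table (5,3;2,7)
  e <- enrichment_test(rep(c(TRUE, FALSE), c(5, 3)),
                       rep(c(TRUE, FALSE), c(2, 7)))
  k <- 0:7                        # feature-in-A count given fixed margins
  probs <- dhyper(k, m = 7, n = 10, k = 8)
  p_brute <- sum(probs[probs <= dhyper(5, 7, 10, 8) * (1 + 1e-7)])
  expect_equal(e$p, p_brute, tolerance = 1e-10)
  # zero margin: Haldane-Anscombe correction, OR still finite
  expect_message(z <- enrichment_test(rep(TRUE, 5), rep(c(TRUE, FALSE),
                                                        c(3, 4))),
                 "Haldane")
  expect_true(is.finite(z$odds_ratio))
})

test_that("enrichment curve spans the alpha grid", {
  set.seed(34)
  curve <- enrichment_curve(runif(500)^2, runif(500))
  expect_equal(nrow(curve), 12)
  expect_true(all(curve$alpha >= 1e-20 & curve$alpha <= 0.05))
})
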