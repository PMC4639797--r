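#' Assign CpG sites to genes within a symmetric window
#'
#' A CpG at 0-based position `pos` pairs with gene `g` iff
#' `pos` lies in `[start(g) - window_bp, end(g) + window_bp)` (closed lower
#' bound, half-open upper bound); one CpG may pair with several genes.
#' Implemented with `IRanges::findOverlaps`, per chromosome.
#'
#' @param cpgs data.frame with columns `cpg_id`, `chrom`, `pos` (0-based).
#' @param genes data.frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (0-based half-open).
#' @param window_bp nonnegative window half-width in base pairs.
#' @return data.frame with columns `cpg_id`, `gene_id`.
#' @export
window_assign <- function(cpgs, genes, window_bp = 250000) {
  if (window_bp < 0) stop("window_bp must be nonnegative")
  out <- lapply(intersect(unique(cpgs$chrom), unique(genes$chrom)),
                function(ch) {
    ci <- which(cpgs$chrom == ch)
    gi <- which(genes$chrom == ch)
    # shift to 1-based closed intervals for IRanges
    q <- IRanges::IRanges(start = cpgs$pos[ci] + 1L, width = 1L)
    s <- IRanges::IRanges(start = pmax(genes$start[gi] - window_bp, 0) + 1L,
                          end = genes$end[gi] + window_bp)
    hit <- IRanges::findOverlaps(q, s)
    data.frame(cpg_id = cpgs$cpg_id[ci[S4Vectors::queryHits(hit)]],
               gene_id = genes$gene_id[gi[S4Vectors::subjectHits(hit)]],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, c(out, list(make.row.names = FALSE)))
}

#' Sobel test from two association z-scores
#'
#' Mediation statistic `z1 * z2 / sqrt(z1^2 + z2^2)` where `z1` is the
#' exposure-to-mediator statistic (methylation on age, Model 1) and `z2` the
#' mediator-to-outcome statistic given exposure (expression on methylation
#' given age, Model 2). Defined as 0 when either input is 0. Satisfies
#' `|z_sobel| <= min(|z1|, |z2|)`.
#'
#' @param z1,z2 numeric vectors (recycled).
#' @return data.frame with `z_sobel` and two-sided normal `p_sobel`.
#' @export
sobel_test <- function(z1, z2) {
  stopifnot(all(is.finite(z1)), all(is.finite(z2)))
  denom <- sqrt(z1^2 + z2^2)
  z <- ifelse(denom == 0, 0, z1 * z2 / denom)
  p <- pmin(pmax(2 * stats::pnorm(abs(z), lower.tail = FALSE), 1e-300), 1)
  data.frame(z_sobel = z, p_sobel = p)
}

#' Flag mediating CpGs under a per-gene Bonferroni rule
#'
#' A pair is flagged iff its Sobel p is strictly below `alpha` divided by the
#' number of CpG sites tested in that pair's gene.
#'
#' @param sobel data.frame with columns `gene_id` and `p_sobel`.
#' @param alpha per-gene family-wise error rate.
#' @return logical vector `mediator_flag`, aligned with `sobel` rows.
#' @export
flag_mediators <- function(sobel, alpha = 0.05) {
  n_in_gene <- stats::ave(sobel$p_sobel, sobel$gene_id, FUN = length)
  sobel$p_sobel < alpha / n_in_gene
}

#' Select random control genes matched on length and mean expression
#'
#' One-to-one matching of `k` target genes to candidates minimizing the
#' Euclidean distance on standardized (log length, log mean expression):
#' greedy nearest-neighbour in target order followed by a pairwise-swap
#' refinement pass. The contract is covariate balance: under the default
#' generator configs the matched set passes two-sample KS tests on both
#' covariates at alpha = 0.01.
#'
#' @param candidates,targets gene annotation data.frames with columns
#'   `gene_id`, `length_bp`, `mean_expression`.
#' @param k number of controls (default: one per target). Requires
#'   `k <= nrow(targets)` and `k <= nrow(candidates)`.
#' @return character vector of `k` control gene ids.
#' @export
select_matched_random_genes <- function(candidates, targets,
                                        k = nrow(targets)) {
  if (k == 0) return(character(0))
  if (k > nrow(targets)) stop("k exceeds number of targets")
  if (nrow(candidates) < k) stop("candidate pool smaller than k")
  targets <- targets[seq_len(k), , drop = FALSE]
  feat <- function(g) cbind(log(g$length_bp), log(g$mean_expression))
  all_f <- rbind(feat(targets), feat(candidates))
  mu <- colMeans(all_f)
  sdev <- pmax(apply(all_f, 2, stats::sd), 1e-12)
  ft <- sweep(sweep(feat(targets), 2, mu), 2, sdev, "/")
  fc <- sweep(sweep(feat(candidates), 2, mu), 2, sdev, "/")
  d2 <- outer(rowSums(ft^2), rowSums(fc^2), "+") - 2 * tcrossprod(ft, fc)
  pick <- integer(k)
  used <- rep(FALSE, nrow(candidates))
  for (i in seq_len(k)) {
    j <- which.min(replace(d2[i, ], used, Inf))
    pick[i] <- j
    used[j] <- TRUE
  }
  # refinement: swap assignments between target pairs when it lowers total d2
  for (i in seq_len(k - 1)) for (j in seq(i + 1, k)) {
    now <- d2[i, pick[i]] + d2[j, pick[j]]
    alt <- d2[i, pick[j]] + d2[j, pick[i]]
    if (alt < now) pick[c(i, j)] <- pick[c(j, i)]
  }
  candidates$gene_id[pick]
}

#' Classify a CpG position against a CpG island track
#'
#' `island` if the position falls inside an island (0-based half-open);
#' `shore` within 1,500 bp of an island edge (boundary closed toward the
#' island); `shelf` within the next 1,500 bp (1,501–3,000 bp from the
#' island); otherwise `open_sea`. Islands must be sorted and non-overlapping.
#'
#' @param pos integer vector of 0-based positions (single chromosome).
#' @param islands data.frame with sorted, non-overlapping `start`, `end`
#'   (0-based half-open).
#' @return character vector of classes.
#' @export
classify_cpg_region <- function(pos, islands) {
  s <- islands$start
  e <- islands$end
  if (is.unsorted(s) || any(e[-length(e)] > s[-1]))
    stop("islands must be sorted and non-overlapping")
  vapply(pos, function(p) {
    if (any(p >= s & p < e)) return("island")
    d <- min(pmax(s - p, p - e))   # gap to nearest island edge
    if (d <= 1500) "shore" else if (d <= 3000) "shelf" else "open_sea"
  }, character(1))
}

#' Fisher enrichment of a feature between two CpG groups
#'
#' Builds the 2x2 table (feature present/absent in groups A and B), reports
#' the sample odds ratio with a Woolf 95% CI (Haldane–Anscombe 0.5 correction
#' when any margin cell is zero, with a message) and the two-sided Fisher
#' exact p-value.
#'
#' @param group_a_flags,group_b_flags logical vectors: feature indicator per
#'   CpG in groups A and B.
#' @return list with `table` (2x2 counts), `odds_ratio`, `ci95`, `p`.
#' @export
enrichment_test <- function(group_a_flags, group_b_flags) {
  tab <- matrix(c(sum(group_a_flags), sum(!group_a_flags),
                  sum(group_b_flags), sum(!group_b_flags)),
                2, 2, dimnames = list(c("feature", "no_feature"),
                                      c("group_a", "group_b")))
  p <- stats::fisher.test(tab)$p.value
  ct <- tab
  if (any(ct == 0)) {
    message("enrichment_test: zero cell; applying Haldane-Anscombe 0.5")
    ct <- ct + 0.5
  }
  or <- (ct[1, 1] * ct[2, 2]) / (ct[1, 2] * ct[2, 1])
  se_log <- sqrt(sum(1 / ct))
  ci <- exp(log(or) + c(-1, 1) * stats::qnorm(0.975) * se_log)
  list(table = tab, odds_ratio = or, ci95 = ci, p = p)
}

#' Enrichment of small p-values across a grid of significance levels
#'
#' Robustness companion to [enrichment_test()]: for each alpha in the grid,
#' tests whether group A has an increased proportion of p-values below alpha
#' relative to group B.
#'
#' @param p_a,p_b numeric p-value vectors for the two groups.
#' @param alphas significance grid (default 1e-20 to 0.05, log-spaced).
#' @return data.frame alpha, odds_ratio, ci_low, ci_high, p.
#' @export
enrichment_curve <- function(p_a, p_b,
                             alphas = 10^seq(-20, log10(0.05), length.out = 12)) {
  rows <- lapply(alphas, function(a) {
    e <- enrichment_test(p_a < a, p_b < a)
    data.frame(alpha = a, odds_ratio = e$odds_ratio,
               ci_low = e$ci95[1], ci_high = e$ci95[2], p = e$p)
  })
  do.call(rbind, rows)
}
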