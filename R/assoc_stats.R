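#' Pearson chi-square test of independence
#'
#' Chi-square without continuity correction, df = (r-1)(c-1). Warns when any
#' expected count is below 5 (the usual validity caveat; see
#' [contingency_test()] for the automatic Fisher fallback).
#'
#' @param table r x c matrix of non-negative integer counts, r, c >= 2.
#' @return list with `statistic`, `df`, `p`, `expected`.
#' @export
chi_square_test <- function(table) {
  check_contingency(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5))
    warning("expected count(s) < 5; chi-square approximation may be poor")
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(res$statistic), df = unname(res$parameter),
       p = res$p.value, expected = expected)
}

check_contingency <- function(table) {
  if (!is.matrix(table) || nrow(table) < 2 || ncol(table) < 2)
    stop("need an r x c matrix with r, c >= 2")
  if (any(table < 0) || any(table != round(table)))
    stop("counts must be non-negative integers")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0))
    stop("zero row or column margin")
  invisible(table)
}

#' Fisher exact test for r x c tables
#'
#' Exact conditional test by the point-probability method: the p-value sums
#' the probabilities of all tables with the observed margins whose
#' hypergeometric probability does not exceed that of the observed table.
#' Exact evaluation is limited to small tables (total <= 200 and at most
#' 4 x 4); larger tables require `monte_carlo = TRUE`, which uses seeded
#' replicate sampling of tables with fixed margins.
#'
#' @param table r x c count matrix.
#' @param monte_carlo use Monte Carlo p-value for large tables.
#' @param B number of Monte Carlo replicates.
#' @return p-value.
#' @export
fisher_exact_rxc <- function(table, monte_carlo = FALSE, B = 10000) {
  check_contingency(table)
  if (!monte_carlo && (sum(table) > 200 || nrow(table) > 4 || ncol(table) > 4))
    stop("table too large for exact enumeration; use monte_carlo = TRUE")
  if (monte_carlo)
    return(stats::fisher.test(table, simulate.p.value = TRUE, B = B)$p.value)
  min(stats::fisher.test(table, workspace = 2e6)$p.value, 1)
}

#' Mixed-test group comparison for a contingency table
#'
#' Applies the expected-count rule used for clinical characteristics tables:
#' Fisher exact when any expected count is below 5, otherwise Pearson
#' chi-square without continuity correction.
#'
#' @param table r x c count matrix.
#' @return list with `p` and `test` ("fisher" or "chisq").
#' @export
contingency_test <- function(table) {
  check_contingency(table)
  expected <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(expected < 5))
    list(p = fisher_exact_rxc(table), test = "fisher")
  else
    list(p = chi_square_test(table)$p, test = "chisq")
}

#' Benjamini-Hochberg step-up adjustment
#'
#' @param p vector of p-values in [0, 1] (NA allowed, propagated).
#' @return q-values in input order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Wilcoxon rank-sum test
#'
#' Exact two-sided p when the smaller sample has at most 10 observations and
#' there are no ties; otherwise normal approximation with tie and continuity
#' correction.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `statistic` (W) and `p`.
#' @export
wilcoxon_rank_sum <- function(x, y) {
  if (!length(x) || !length(y)) stop("empty sample")
  exact <- min(length(x), length(y)) <= 10 && !anyDuplicated(c(x, y))
  res <- suppressWarnings(stats::wilcox.test(x, y, exact = exact,
                                             correct = TRUE))
  list(statistic = unname(res$statistic), p = res$p.value)
}

#' Spearman rank correlation
#'
#' Pearson correlation of mid-ranks (tie-aware), p from the t approximation.
#'
#' @param x,y paired numeric vectors, >= 3 finite pairs.
#' @return list with `rho` and `p`.
#' @export
spearman_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  if (sum(ok) < 3) stop("need >= 3 paired finite observations")
  x <- x[ok]; y <- y[ok]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("constant vector")
  res <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                          exact = FALSE))
  list(rho = unname(res$estimate), p = res$p.value)
}

#' Mutation-cluster association and pairwise co-occurrence
#'
#' Genes mutated in fewer than `min_freq` of samples are excluded. For each
#' remaining gene, a Fisher exact test on the mutated/wild-type x cluster
#' table; BH across genes. For each remaining gene pair, the 2 x 2 Fisher
#' test and cross-product odds ratio (OR > 1 co-occurrence, OR < 1 mutual
#' exclusivity); a Haldane 0.5 correction is applied to the OR only when a
#' cell is zero, and flagged.
#'
#' @param mutations [mutation_matrix()] (genes x samples).
#' @param clusters named cluster labels (0 = unassigned, excluded); names are
#'   sample ids.
#' @param min_freq frequency filter (default 0.1).
#' @param q_cut significance threshold on q (default 0.1), reported as flags.
#' @return list with data.frames `cluster_association` (gene, n_mutated,
#'   p, q, significant) and `co_occurrence` (gene_a, gene_b, odds_ratio,
#'   zero_cell_corrected, p, q, significant).
#' @export
mutation_analysis <- function(mutations, clusters, min_freq = 0.1,
                              q_cut = 0.1) {
  stopifnot(!is.null(names(clusters)))
  keep_s <- names(clusters)[clusters > 0]
  keep_s <- intersect(keep_s, colnames(mutations))
  cl <- clusters[keep_s]
  if (length(unique(cl)) < 2) stop("need >= 2 clusters")
  m <- mutations[, keep_s, drop = FALSE]
  freq <- rowMeans(m)
  genes <- rownames(m)[freq >= min_freq]
  if (!length(genes)) {
    warning("no gene passes the ", min_freq * 100, "% frequency filter")
    return(list(cluster_association = data.frame(), co_occurrence = data.frame()))
  }
  p <- vapply(genes, function(g) {
    tab <- table(factor(m[g, ], levels = 0:1), cl)
    if (any(rowSums(tab) == 0)) return(NA_real_)
    fisher_exact_rxc(unclass(tab))
  }, 0)
  assoc <- data.frame(gene = genes, n_mutated = rowSums(m[genes, , drop = FALSE]),
                      p = p, q = bh_adjust(p), row.names = NULL)
  assoc$significant <- !is.na(assoc$q) & assoc$q < q_cut

  pairs <- if (length(genes) >= 2) utils::combn(genes, 2) else
    matrix(character(), 2, 0)
  co <- data.frame(gene_a = pairs[1, ], gene_b = pairs[2, ],
                   odds_ratio = NA_real_, zero_cell_corrected = FALSE,
                   p = NA_real_)
  for (i in seq_len(ncol(pairs))) {
    a <- m[pairs[1, i], ]; b <- m[pairs[2, i], ]
    tab <- matrix(c(sum(a & b), sum(a & !b), sum(!a & b), sum(!a & !b)), 2, 2)
    corrected <- any(tab == 0)
    tt <- if (corrected) tab + 0.5 else tab
    co$odds_ratio[i] <- (tt[1, 1] * tt[2, 2]) / (tt[1, 2] * tt[2, 1])
    co$zero_cell_corrected[i] <- corrected
    co$p[i] <- fisher_exact_rxc(tab)
  }
  co$q <- bh_adjust(co$p)
  co$significant <- !is.na(co$q) & co$q < q_cut
  list(cluster_association = assoc, co_occurrence = co)
}

#' Protein differential expression between two groups
#'
#' Per protein: difference in mean expression (A minus B) and a Wilcoxon
#' rank-sum p; BH across proteins. Selection: up if the difference exceeds
#' the 75th percentile of all per-protein differences and q < q_cut; down if
#' below the 25th percentile and q < q_cut.
#'
#' @param proteins [protein_matrix()].
#' @param samples_a,samples_b sample id vectors (>= 2 each).
#' @param q_cut FDR threshold (default 0.1).
#' @return data.frame with protein, diff_mean, p, q, up, down; percentile
#'   thresholds in attributes `upper_cut`, `lower_cut`.
#' @export
rppa_differential <- function(proteins, samples_a, samples_b, q_cut = 0.1) {
  if (length(samples_a) < 2 || length(samples_b) < 2)
    stop("each group needs >= 2 samples")
  A <- proteins[, samples_a, drop = FALSE]
  B <- proteins[, samples_b, drop = FALSE]
  d <- rowMeans(A) - rowMeans(B)
  p <- vapply(rownames(proteins),
              function(pr) wilcoxon_rank_sum(A[pr, ], B[pr, ])$p, 0)
  q <- bh_adjust(p)
  hi <- stats::quantile(d, 0.75); lo <- stats::quantile(d, 0.25)
  out <- data.frame(protein = rownames(proteins), diff_mean = d, p = p, q = q,
                    up = d > hi & q < q_cut, down = d < lo & q < q_cut,
                    row.names = NULL)
  attr(out, "upper_cut") <- unname(hi)
  attr(out, "lower_cut") <- unname(lo)
  out
}
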