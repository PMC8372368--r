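#' Gene-set test on per-gene statistics
#'
#' Two-sample t comparison of the member-gene statistics against the
#' non-member (background) statistics, two-sided; the mean member statistic
#' gives the reported effect and its direction relative to the background
#' mean. BH across tested sets. Sets with fewer than 2 member genes present
#' in the statistic vector are skipped with a warning.
#'
#' @param stats_vec named numeric vector of per-gene statistics (e.g. the DE
#'   t statistic).
#' @param collection a [gene_set_collection()].
#' @param q_cut significance threshold (default 0.1).
#' @return data.frame with set, n_genes, mean_stat, direction (+1/-1), p, q,
#'   significant.
#' @export
gsea_set_test <- function(stats_vec, collection, q_cut = 0.1) {
  if (!length(collection)) stop("empty gene set collection")
  stopifnot(!is.null(names(stats_vec)))
  universe <- names(stats_vec)
  rows <- lapply(names(collection), function(nm) {
    memb <- intersect(collection[[nm]], universe)
    if (length(memb) < 2) return(NULL)
    inset <- stats_vec[memb]
    outset <- stats_vec[setdiff(universe, memb)]
    tt <- stats::t.test(inset, outset)
    data.frame(set = nm, n_genes = length(memb), mean_stat = mean(inset),
               direction = sign(mean(inset) - mean(outset)), p = tt$p.value)
  })
  skipped <- names(collection)[vapply(rows, is.null, TRUE)]
  if (length(skipped))
    warning("skipped set(s) with < 2 genes in the statistic vector: ",
            paste(skipped, collapse = ", "))
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no testable set (all below 2 member genes)")
  out$q <- bh_adjust(out$p)
  out$significant <- out$q < q_cut
  rownames(out) <- NULL
  out
}

#' Single-sample GSEA activity scores
#'
#' Per sample, genes are ranked by expression (descending, ties broken by
#' stable gene order). The score of a set is the sum over rank positions of
#' the difference between the weighted empirical CDF of member genes (weight
#' = rank position normalized to (0, 1], raised to `alpha`) and the
#' unweighted ECDF of non-member genes. At `alpha = 0` the score depends
#' only on the within-sample ranking. Sets are intersected with the matrix
#' genes; empty sets are skipped with a warning, and a set covering every
#' gene is an error (empty complement).
#'
#' @param log2mat log2 [expression_matrix()] (any monotone per-sample scale
#'   works at alpha = 0).
#' @param collection a [gene_set_collection()].
#' @param alpha rank weight exponent (default 0.25).
#' @param normalize min-max normalize each set's scores across samples
#'   (default FALSE).
#' @return matrix of scores, sets x samples.
#' @export
ssgsea_score <- function(log2mat, collection, alpha = 0.25,
                         normalize = FALSE) {
  if (!length(collection)) stop("empty gene set collection")
  genes <- rownames(log2mat)
  N <- length(genes)
  memb_idx <- lapply(collection, function(g) which(genes %in% g))
  empty <- names(collection)[lengths(memb_idx) == 0]
  if (length(empty)) {
    warning("set(s) with no gene in the matrix skipped: ",
            paste(empty, collapse = ", "))
    memb_idx <- memb_idx[lengths(memb_idx) > 0]
  }
  if (!length(memb_idx)) stop("no scorable set")
  full <- names(memb_idx)[lengths(memb_idx) == N]
  if (length(full))
    stop("set(s) covering all genes (empty complement): ",
         paste(full, collapse = ", "))
  scores <- matrix(NA_real_, length(memb_idx), ncol(log2mat),
                   dimnames = list(names(memb_idx), colnames(log2mat)))
  w_all <- ((N:1) / N)^alpha                    # weight by sorted position
  for (j in seq_len(ncol(log2mat))) {
    ord <- order(log2mat[, j], decreasing = TRUE)  # stable: ties by gene order
    for (s in seq_along(memb_idx)) {
      ind <- ord %in% memb_idx[[s]]
      w <- w_all * ind
      cdf_in <- cumsum(w) / sum(w)
      cdf_out <- cumsum(!ind) / (N - sum(ind))
      scores[s, j] <- sum(cdf_in - cdf_out)
    }
  }
  if (normalize) {
    rng <- apply(scores, 1, function(x) diff(range(x)))
    scores <- (scores - apply(scores, 1, min)) / ifelse(rng == 0, 1, rng)
  }
  scores
}

#' Compare pathway activity between two groups
#'
#' Wilcoxon rank-sum per set, BH across sets; direction from the median
#' difference (group A minus group B).
#'
#' @param scores set x sample score matrix from [ssgsea_score()].
#' @param samples_a,samples_b sample id vectors (>= 2 each).
#' @param q_cut significance threshold (default 0.05).
#' @return data.frame with set, median_diff, direction, p, q, significant.
#' @export
compare_pathway_activity <- function(scores, samples_a, samples_b,
                                     q_cut = 0.05) {
  if (length(samples_a) < 2 || length(samples_b) < 2)
    stop("each group needs >= 2 samples")
  A <- scores[, samples_a, drop = FALSE]
  B <- scores[, samples_b, drop = FALSE]
  md <- apply(A, 1, stats::median) - apply(B, 1, stats::median)
  p <- vapply(rownames(scores),
              function(s) wilcoxon_rank_sum(A[s, ], B[s, ])$p, 0)
  q <- bh_adjust(p)
  data.frame(set = rownames(scores), median_diff = md,
             direction = sign(md), p = p, q = q, significant = q < q_cut,
             row.names = NULL)
}

#' Group-2-likeness score and median stratification
#'
#' Scores each sample as ssGSEA(up signature) minus ssGSEA(down signature)
#' and splits the cohort at the median (ties and, for odd n, the median
#' sample go to the high stratum). Used to transfer the discovery grouping
#' to external cohorts.
#'
#' @param log2mat expression matrix of the cohort to score.
#' @param signature list with `up` and `down` gene vectors (from
#'   [select_signature_genes()] or a 2-set GMT).
#' @param alpha ssGSEA rank weight exponent.
#' @return data.frame with sample, up_score, down_score, score, stratum.
#' @export
group_likeness_score <- function(log2mat, signature, alpha = 0.25) {
  for (side in c("up", "down")) {
    g <- signature[[side]]
    if (!length(g)) stop("empty ", side, " signature set")
    lost <- setdiff(g, rownames(log2mat))
    if (length(lost) == length(g))
      stop(side, " set empty after intersection; lost genes: ",
           paste(utils::head(lost, 10), collapse = ", "),
           if (length(lost) > 10) " ..." else "")
  }
  sc <- ssgsea_score(log2mat,
                     gene_set_collection(list(up = signature$up,
                                              down = signature$down)),
                     alpha = alpha)
  score <- sc["up", ] - sc["down", ]
  data.frame(sample = colnames(log2mat),
             up_score = sc["up", ], down_score = sc["down", ],
             score = score, stratum = score_stratify_median(score),
             row.names = NULL)
}

#' Median split of a score vector
#'
#' high = score >= median, low = rest; with odd n the median sample goes to
#' the high stratum.
#'
#' @param score numeric vector, >= 4 samples, not all identical.
#' @return factor with levels `"low"`, `"high"` (names preserved).
#' @export
score_stratify_median <- function(score) {
  if (length(score) < 4) stop("need >= 4 samples to stratify")
  if (length(unique(score)) == 1) stop("all scores identical; no split possible")
  f <- factor(ifelse(score >= stats::median(score), "high", "low"),
              levels = c("low", "high"))
  names(f) <- names(score)
  f
}
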