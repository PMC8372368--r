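#' Median-of-ratios normalization
#'
#' Size factor for sample j is the median over genes (restricted to genes
#' with a positive count in every sample, i.e. finite log geometric mean) of
#' count_gj / geometric-mean_g; normalized counts are counts / size factor.
#' The median is taken on the log-ratio scale (so with an even number of
#' reference genes the two central ratios are combined geometrically), the
#' convention of the standard RNA-seq implementations.
#'
#' @param counts raw-count [expression_matrix()].
#' @return list with `normalized` (scale `normalized_counts`) and
#'   `size_factors` (named numeric).
#' @export
normalize_median_of_ratios <- function(counts) {
  require_scale(counts, "raw_counts")
  if (any(colSums(counts) == 0))
    stop("sample(s) with all-zero counts: ",
         paste(colnames(counts)[colSums(counts) == 0], collapse = ", "))
  loggeo <- rowMeans(log(counts))
  use <- is.finite(loggeo)
  if (!any(use))
    stop("no gene has a positive count in every sample; ",
         "median-of-ratios is undefined (consider a pseudo-reference fallback)")
  sf <- apply(counts[use, , drop = FALSE], 2,
              function(x) exp(stats::median(log(x) - loggeo[use])))
  names(sf) <- colnames(counts)
  norm <- sweep(unclass_expr(counts), 2, sf, "/")
  list(normalized = expression_matrix(norm, "normalized_counts"),
       size_factors = sf)
}

# strip the scale attribute so sweep() etc. return plain matrices
unclass_expr <- function(x) { attr(x, "scale") <- NULL; x }

#' Log2 transform normalized counts
#'
#' @param normalized an [expression_matrix()] with scale `normalized_counts`.
#' @param pseudocount positive offset added before log2 (default 1).
#' @return [expression_matrix()] with scale `log2`.
#' @export
log2_transform <- function(normalized, pseudocount = 1) {
  require_scale(normalized, "normalized_counts")
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  if (any(normalized < 0)) stop("negative values in normalized matrix")
  expression_matrix(log2(unclass_expr(normalized) + pseudocount), "log2")
}

#' Select variable genes
#'
#' Either all genes with sample variance above `threshold`, or the `top_n`
#' highest-variance genes. Variance uses the n-1 denominator.
#'
#' @param log2mat [expression_matrix()] on the log2 scale.
#' @param threshold variance threshold (exclusive); mutually exclusive with
#'   `top_n`.
#' @param top_n number of top-variance genes.
#' @return character vector of gene ids.
#' @export
variance_filter <- function(log2mat, threshold = NULL, top_n = NULL) {
  require_scale(log2mat, "log2")
  if (is.null(threshold) == is.null(top_n))
    stop("supply exactly one of `threshold` or `top_n`")
  v <- row_vars(log2mat)
  if (!is.null(top_n)) {
    if (top_n > nrow(log2mat))
      stop("top_n exceeds the number of genes")
    return(rownames(log2mat)[order(v, decreasing = TRUE)[seq_len(top_n)]])
  }
  rownames(log2mat)[v > threshold]
}

row_vars <- function(m) {
  mu <- rowMeans(m)
  rowSums((m - mu)^2) / (ncol(m) - 1)
}

#' Two-group differential expression (Welch t on log2 values)
#'
#' Per gene: log2 fold change = mean(A) - mean(B) on the log2 scale, Welch
#' two-sample t statistic with Satterthwaite degrees of freedom, two-sided
#' p, and Benjamini-Hochberg q. Genes with zero variance in both groups get
#' statistic 0 and p 1.
#'
#' @param log2mat log2 [expression_matrix()].
#' @param samples_a,samples_b disjoint character vectors of sample ids, each
#'   of length >= 2.
#' @return data.frame with columns gene, log2FC, stat, p, q, meanA, meanB.
#' @export
differential_expression <- function(log2mat, samples_a, samples_b) {
  require_scale(log2mat, "log2")
  if (length(intersect(samples_a, samples_b)))
    stop("groups overlap: ", paste(intersect(samples_a, samples_b), collapse = ", "))
  if (length(samples_a) < 2 || length(samples_b) < 2)
    stop("each group needs >= 2 samples")
  A <- log2mat[, samples_a, drop = FALSE]
  B <- log2mat[, samples_b, drop = FALSE]
  na <- ncol(A); nb <- ncol(B)
  ma <- rowMeans(A); mb <- rowMeans(B)
  va <- row_vars(A); vb <- row_vars(B)
  se2 <- va / na + vb / nb
  stat <- ifelse(se2 > 0, (ma - mb) / sqrt(se2), 0)
  df <- ifelse(se2 > 0,
               se2^2 / ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1)), 1)
  p <- ifelse(se2 > 0, 2 * stats::pt(-abs(stat), df), 1)
  data.frame(gene = rownames(log2mat), log2FC = ma - mb, stat = stat,
             p = p, q = bh_adjust(p), meanA = ma, meanB = mb,
             row.names = NULL)
}

#' Extract up/down signature gene sets from a DE result
#'
#' up = log2FC > lfc_cut and q < q_cut; down = log2FC < -lfc_cut and
#' q < q_cut. Empty sets are allowed.
#'
#' @param de result of [differential_expression()].
#' @param lfc_cut log2 fold-change threshold (default 2).
#' @param q_cut FDR threshold (default 0.05).
#' @return list with `up`, `down` gene vectors and `thresholds`.
#' @export
select_signature_genes <- function(de, lfc_cut = 2, q_cut = 0.05) {
  up <- de$gene[de$log2FC > lfc_cut & de$q < q_cut]
  down <- de$gene[de$log2FC < -lfc_cut & de$q < q_cut]
  if (!length(up)) message("signature: no upregulated genes at thresholds")
  if (!length(down)) message("signature: no downregulated genes at thresholds")
  list(up = up, down = down,
       thresholds = c(lfc_cut = lfc_cut, q_cut = q_cut))
}
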