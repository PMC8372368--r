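#' Per-gene regression screen for FAB-associated expression
#'
#' For each gene, ordinary least squares of log2 expression on indicator
#' variables for FAB M2, M4 and M5 with M1 as the reference; a two-sided t
#' p-value per contrast coefficient; BH adjustment performed within each
#' contrast across genes. A gene is flagged FAB-associated when the minimum
#' q over the three contrasts is below `q_cut`.
#'
#' @param log2mat log2 [expression_matrix()].
#' @param fab FAB labels (M1/M2/M4/M5) aligned with the matrix columns;
#'   M1 must be present and every observed level needs >= 2 samples.
#' @param q_cut per-contrast FDR threshold (default 0.05).
#' @return list with `coefficients`, `p_values`, `q_values` (gene x contrast
#'   matrices, contrasts M2/M4/M5 vs M1) and `fab_associated` (named logical).
#' @export
fit_fab_association <- function(log2mat, fab, q_cut = 0.05) {
  require_scale(log2mat, "log2")
  stopifnot(length(fab) == ncol(log2mat))
  fab <- factor(fab, levels = c("M1", "M2", "M4", "M5"))
  if (anyNA(fab)) stop("unknown FAB level present")
  cnt <- table(fab)
  if (cnt[["M1"]] == 0) stop("reference level M1 missing")
  low <- names(cnt)[cnt > 0 & cnt < 2]
  if (length(low)) stop("FAB level(s) with < 2 samples: ",
                        paste(low, collapse = ", "))
  X <- stats::model.matrix(~fab)
  XtXi <- solve(crossprod(X))
  B <- t(XtXi %*% crossprod(X, t(log2mat)))          # genes x coefficients
  fitted <- B %*% t(X)
  df <- ncol(log2mat) - ncol(X)
  sigma2 <- rowSums((log2mat - fitted)^2) / df
  sigma2[sigma2 < 1e-18] <- 0          # constant genes: exact-zero residual
  contrasts <- colnames(X)[-1]
  se <- sqrt(outer(sigma2, diag(XtXi)[-1]))
  coef <- B[, -1, drop = FALSE]
  tstat <- ifelse(se > 0, coef / se, 0)
  p <- 2 * stats::pt(-abs(tstat), df)
  p[se == 0] <- 1
  q <- apply(p, 2, bh_adjust)
  nice <- sub("^fab", "", contrasts)
  dimnames(coef) <- dimnames(p) <- dimnames(q) <-
    list(rownames(log2mat), paste0(nice, "_vs_M1"))
  flag <- apply(q, 1, min) < q_cut
  list(coefficients = coef, p_values = p, q_values = q, fab_associated = flag)
}

#' Exclude FAB-associated genes, keep the high-variance remainder
#'
#' @param log2mat log2 [expression_matrix()].
#' @param fab_assoc result of [fit_fab_association()].
#' @param threshold variance threshold (default 5, log2 scale).
#' @return character vector of selected gene ids.
#' @export
exclude_and_select <- function(log2mat, fab_assoc, threshold = 5) {
  keep <- !fab_assoc$fab_associated[rownames(log2mat)]
  v <- row_vars(log2mat)
  sel <- rownames(log2mat)[keep & v > threshold]
  if (!length(sel))
    stop("no gene survives exclusion + variance > ", threshold,
         "; consider lowering the threshold")
  sel
}

#' Hierarchical clustering of samples (Euclidean, complete linkage)
#'
#' Deterministic given input order (stats::hclust breaks distance ties by
#' the smallest merge index pair).
#'
#' @param log2mat log2 [expression_matrix()], usually restricted to a
#'   selected gene subset; >= 3 samples.
#' @return an `hclust` object; the distance matrix is attached as
#'   attribute `"dist"`.
#' @export
hierarchical_dendrogram <- function(log2mat) {
  if (ncol(log2mat) < 3) stop("need >= 3 samples")
  if (any(!is.finite(log2mat))) stop("non-finite values in matrix")
  d <- stats::dist(t(log2mat), method = "euclidean")
  hc <- stats::hclust(d, method = "complete")
  attr(hc, "dist") <- d
  hc
}

# leaf sets per internal merge node of an hclust tree
merge_members <- function(hc) {
  memb <- vector("list", nrow(hc$merge))
  for (i in seq_len(nrow(hc$merge))) {
    m <- hc$merge[i, ]
    memb[[i]] <- c(if (m[1] < 0) -m[1] else memb[[m[1]]],
                   if (m[2] < 0) -m[2] else memb[[m[2]]])
  }
  memb
}

#' Dynamic tree cut
#'
#' Adaptive dendrogram cut: a static cut at the `cut_height_quantile` of the
#' merge heights yields initial branches; each branch is then inspected
#' recursively and split whenever both sub-branches have at least
#' `min_cluster_size` members and the merge height exceeds `gap_factor`
#' times the taller sub-branch (a height-gap criterion, so tight clusters
#' are not fragmented and the result coincides with the static cut on
#' well-separated data). Branches below the minimum size are merged into
#' the nearest cluster by average distance when that distance is within the
#' cut height, otherwise labeled 0 (unassigned). Cluster labels are
#' renumbered by decreasing size.
#'
#' @param hc dendrogram from [hierarchical_dendrogram()] (or any `hclust`
#'   with a `"dist"` attribute or an explicit `d`).
#' @param min_cluster_size minimum cluster size (default 8).
#' @param cut_height_quantile quantile of merge heights for the static cut
#'   (default 0.99).
#' @param gap_factor height-gap ratio required to split a branch (default 2).
#' @param d optional distance object matching `hc`.
#' @return list with `labels` (named integer, 0 = unassigned), `hc`,
#'   `parameters`.
#' @export
dynamic_tree_cut <- function(hc, min_cluster_size = 8,
                             cut_height_quantile = 0.99, gap_factor = 2,
                             d = NULL) {
  if (is.null(d)) d <- attr(hc, "dist")
  if (is.null(d)) stop("supply the distance matrix used to build the tree")
  n <- length(hc$order)
  if (min_cluster_size > n) stop("min_cluster_size exceeds sample count")
  cut_h <- stats::quantile(hc$height, cut_height_quantile, names = FALSE)
  branch <- stats::cutree(hc, h = cut_h)
  memb <- merge_members(hc)
  node_height <- function(k) if (k < 0) 0 else hc$height[k]
  split_rec <- function(node) {
    m <- hc$merge[node, ]
    sizes <- c(if (m[1] < 0) 1L else length(memb[[m[1]]]),
               if (m[2] < 0) 1L else length(memb[[m[2]]]))
    child_h <- c(node_height(m[1]), node_height(m[2]))
    if (min(sizes) >= min_cluster_size &&
        hc$height[node] > gap_factor * max(child_h)) {
      out <- list()
      for (k in 1:2)
        out <- c(out, if (m[k] < 0) list(-m[k]) else split_rec(m[k]))
      out
    } else list(memb[[node]])
  }
  clusters <- list(); small <- list()
  for (b in split(seq_len(n), branch)) {
    parts <- if (length(b) == 1) list(b) else {
      node <- which(vapply(memb, function(x)
        length(x) == length(b) && all(sort(x) == sort(b)), TRUE))
      split_rec(node)
    }
    for (p in parts)
      if (length(p) >= min_cluster_size) clusters <- c(clusters, list(p))
      else small <- c(small, list(p))
  }
  lab <- integer(n)
  if (!length(clusters)) {
    lab[] <- 1L                      # no viable branch: one cluster
  } else {
    dm <- as.matrix(d)
    for (i in seq_along(clusters)) lab[clusters[[i]]] <- i
    for (s in small) {
      avg <- vapply(clusters, function(cl) mean(dm[s, cl]), 0)
      if (min(avg) <= cut_h) lab[s] <- which.min(avg)
    }
    sz <- sort(table(lab[lab > 0]), decreasing = TRUE)
    relab <- stats::setNames(seq_along(sz), names(sz))
    lab <- ifelse(lab > 0, relab[as.character(lab)], 0L)
  }
  names(lab) <- hc$labels
  list(labels = lab, hc = hc,
       parameters = list(distance = "euclidean", linkage = "complete",
                         min_cluster_size = min_cluster_size,
                         cut_height_quantile = cut_height_quantile,
                         gap_factor = gap_factor, cut_height = cut_h))
}

#' Fisher test of cluster membership against lineage
#'
#' Tests the K x 2 table of cluster label versus binary lineage (M1/M2 vs
#' M4/M5); unassigned samples (label 0) are excluded.
#'
#' @param labels named cluster labels (from [dynamic_tree_cut()]).
#' @param lineage binary lineage factor aligned by sample name (or position).
#' @return Fisher p-value.
#' @export
lineage_association_test <- function(labels, lineage) {
  if (!is.null(names(labels)) && !is.null(names(lineage)))
    lineage <- lineage[names(labels)]
  keep <- labels > 0 & !is.na(lineage)
  if (length(unique(labels[keep])) < 2) stop("need >= 2 clusters")
  tab <- table(labels[keep], lineage[keep])
  fisher_exact_rxc(unclass(tab))
}

#' Sensitivity of naive clustering to the number of variable genes
#'
#' For each gene count: select the top-variance genes with no FAB exclusion,
#' cluster, and test the cluster-lineage association.
#'
#' @param log2mat log2 [expression_matrix()].
#' @param fab FAB labels aligned with the columns.
#' @param counts gene counts to sweep (default 1000, 1500, 2000, 2500, 3000).
#' @param ... passed to [dynamic_tree_cut()].
#' @return data.frame with n_genes, K, fisher_p.
#' @export
gene_count_sensitivity <- function(log2mat, fab,
                                   counts = c(1000, 1500, 2000, 2500, 3000),
                                   ...) {
  if (any(counts > nrow(log2mat))) stop("count exceeds number of genes")
  lineage <- fab_lineage(fab)
  out <- lapply(counts, function(k) {
    sel <- variance_filter(log2mat, top_n = k)
    hc <- hierarchical_dendrogram(log2mat[sel, , drop = FALSE])
    ct <- dynamic_tree_cut(hc, ...)
    K <- length(unique(ct$labels[ct$labels > 0]))
    p <- if (K >= 2) lineage_association_test(
      ct$labels, stats::setNames(lineage, colnames(log2mat))) else NA_real_
    data.frame(n_genes = k, K = K, fisher_p = p)
  })
  do.call(rbind, out)
}

#' Full lineage-decoupled clustering
#'
#' Convenience wrapper running the whole core procedure on a log2 matrix:
#' FAB-association screen, exclusion + variance selection, hierarchical
#' clustering, dynamic tree cut, and the lineage-independence Fisher test.
#'
#' @param log2mat log2 [expression_matrix()].
#' @param fab FAB labels aligned with columns.
#' @param variance_threshold variance cut after exclusion (default 5).
#' @param ... passed to [dynamic_tree_cut()].
#' @return list with `labels`, `hc`, `selected_genes`, `fab_association`,
#'   `lineage_p`, `parameters`.
#' @export
decouple_cluster <- function(log2mat, fab, variance_threshold = 5, ...) {
  fa <- fit_fab_association(log2mat, fab)
  sel <- exclude_and_select(log2mat, fa, threshold = variance_threshold)
  hc <- hierarchical_dendrogram(log2mat[sel, , drop = FALSE])
  ct <- dynamic_tree_cut(hc, ...)
  K <- length(unique(ct$labels[ct$labels > 0]))
  p <- if (K >= 2)
    lineage_association_test(ct$labels,
                             stats::setNames(fab_lineage(fab),
                                             colnames(log2mat)))
  else NA_real_
  list(labels = ct$labels, hc = hc, selected_genes = sel,
       fab_association = fa, lineage_p = p, parameters = ct$parameters)
}

#' Adjusted Rand index between two partitions
#'
#' Chance-corrected agreement; used to score recovered clusters against the
#' simulator's latent groups.
#'
#' @param a,b partition label vectors of equal length.
#' @return ARI in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  mclust::adjustedRandIndex(a, b)
}
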