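test_that("FAB regression coefficients equal group mean differences (closed form)", {
  set.seed(8)
  fab <- rep(c("M1", "M2", "M4", "M5"), times = c(5, 6, 7, 6))
  m <- matrix(rnorm(30 * length(fab)), 30, length(fab),
              dimnames = list(sprintf("g%02d", 1:30), sprintf("s%02d", seq_along(fab))))
  l2 <- expression_matrix(m, "log2")
  fa <- fit_fab_association(l2, fab)
  direct <- rowMeans(m[, fab == "M2"]) - rowMeans(m[, fab == "M1"])
  expect_equal(unname(fa$coefficients[, "M2_vs_M1"]), unname(direct),
               tolerance = 1e-10)
  # constant gene: statistic 0, p 1, not flagged
  m2 <- m; m2[1, ] <- 4
  fa2 <- fit_fab_association(expression_matrix(m2, "log2"), fab)
  expect_equal(unname(fa2$p_values[1, ]), c(1, 1, 1))
  expect_false(fa2$fab_associated[[1]])
  # q-values reproduce the reference BH exactly, per contrast
  expect_equal(unname(fa$q_values[, 1]),
               unname(p.adjust(fa$p_values[, 1], "BH")))
  expect_error(fit_fab_association(l2, rep(c("M2", "M4", "M5"), 8)), "M1")
  fab_single <- fab
  fab_single[fab_single == "M5"] <- "M4"
  fab_single[length(fab_single)] <- "M5"      # exactly one M5 sample
  expect_error(fit_fab_association(l2, fab_single), "< 2 samples")
})

test_that("planted lineage gene is flagged with tiny q", {
  set.seed(9)
  n <- 81
  fab <- sample(rep(c("M1", "M2", "M4", "M5"), length.out = n))
  m <- matrix(rnorm(200 * n, sd = 0.5), 200, n,
              dimnames = list(sprintf("g%03d", 1:200), sprintf("s%03d", 1:n)))
  m["g001", fab %in% c("M4", "M5")] <- m["g001", fab %in% c("M4", "M5")] + 5
  fa <- fit_fab_association(expression_matrix(m, "log2"), fab)
  expect_true(fa$fab_associated[["g001"]])
  expect_lt(min(fa$q_values["g001", c("M4_vs_M1", "M5_vs_M1")]), 1e-10)
})

test_that("exclusion + variance selection recovers biology genes, errors when empty", {
  co <- test_cohort()
  fa <- fit_fab_association(co$log2, co$clinical$fab)
  gt <- co$truth$gene_truth
  expect_gte(mean(fa$fab_associated[gt$gene_id[gt$lineage_gene]]), 0.9)
  expect_lte(mean(fa$fab_associated[gt$gene_id[gt$biology_gene]]), 0.1)
  sel <- exclude_and_select(co$log2, fa)
  expect_gte(mean(sel %in% gt$gene_id[gt$biology_gene]), 0.9)

  all_flagged <- fa
  all_flagged$fab_associated[] <- TRUE
  expect_error(exclude_and_select(co$log2, all_flagged), "threshold")
  none <- fa; none$fab_associated[] <- FALSE
  expect_setequal(exclude_and_select(co$log2, none, threshold = -1),
                  rownames(co$log2))
})

test_that("dendrogram merges match a brute-force oracle and basic geometry", {
  # 3 points at mutual distances 1,1,2: first merge joins the distance-1 pair
  m <- rbind(a = c(0, 0), b = c(1, 0), c = c(-1, 0))
  x <- t(m); rownames(x) <- c("d1", "d2"); colnames(x) <- c("a", "b", "c")
  hc <- hierarchical_dendrogram(expression_matrix(x, "log2"))
  expect_equal(hc$height[1], 1)
  expect_setequal(hc$labels[-hc$merge[1, ]], c("a", "b"))

  # duplicated sample merges at height 0
  x2 <- cbind(x, a2 = x[, "a"])
  hc2 <- hierarchical_dendrogram(expression_matrix(x2, "log2"))
  expect_equal(hc2$height[1], 0)

  set.seed(10)
  y <- matrix(rnorm(5 * 8), 5, 8,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:8)))
  hc3 <- hierarchical_dendrogram(expression_matrix(y, "log2"))
  oracle <- brute_complete_linkage_heights(dist(t(y)))
  expect_equal(sort(hc3$height), oracle, tolerance = 1e-10)

  y[1, 1] <- NA
  expect_error(hierarchical_dendrogram(expression_matrix(y, "log2")),
               "non-finite")
})

test_that("dynamic tree cut equals a static 2-cut on two separated blobs", {
  set.seed(11)
  centers <- rbind(rep(0, 5), rep(10, 5))
  x <- rbind(matrix(rnorm(20 * 5, sd = 0.1), 20, 5, byrow = FALSE) +
               matrix(centers[1, ], 20, 5, byrow = TRUE),
             matrix(rnorm(20 * 5, sd = 0.1), 20, 5) +
               matrix(centers[2, ], 20, 5, byrow = TRUE))
  m <- t(x); dimnames(m) <- list(paste0("g", 1:5), paste0("s", 1:40))
  hc <- hierarchical_dendrogram(expression_matrix(m, "log2"))
  ct <- dynamic_tree_cut(hc)
  static <- cutree(hc, k = 2)
  expect_equal(length(unique(ct$labels)), 2)
  expect_equal(adjusted_rand_index(ct$labels, static), 1)
  expect_equal(adjusted_rand_index(ct$labels, rep(1:2, each = 20)), 1)

  # all points identical: a single cluster
  m0 <- matrix(1, 4, 10, dimnames = list(paste0("g", 1:4), paste0("s", 1:10)))
  hc0 <- hierarchical_dendrogram(expression_matrix(m0, "log2"))
  expect_equal(unname(unique(dynamic_tree_cut(hc0)$labels)), 1L)
  expect_error(dynamic_tree_cut(hc0, min_cluster_size = 11), "exceeds")
})

test_that("decoupled clustering recovers the latent groups on the synthetic cohort", {
  co <- test_cohort()
  res <- decouple_cluster(co$log2, co$clinical$fab)
  expect_gte(adjusted_rand_index(res$labels, co$truth$group), 0.8)
  expect_equal(length(unique(res$labels[res$labels > 0])), 3)
  # labels are renumbered by decreasing cluster size
  sz <- table(res$labels[res$labels > 0])
  expect_true(all(diff(as.vector(sz)) <= 0))
  expect_gt(res$lineage_p, 0.01)
})

test_that("cluster labels are invariant to sample permutation (up to renaming)", {
  co <- test_cohort()
  sel <- variance_filter(co$log2, top_n = 300)
  m <- co$log2[sel, ]
  hc1 <- hierarchical_dendrogram(expression_matrix(m, "log2"))
  c1 <- dynamic_tree_cut(hc1)$labels
  set.seed(12)
  perm <- sample(ncol(m))
  hc2 <- hierarchical_dendrogram(expression_matrix(m[, perm], "log2"))
  c2 <- dynamic_tree_cut(hc2)$labels
  expect_equal(adjusted_rand_index(c1[names(c2)], c2), 1)
})

test_that("lineage association test matches enumeration and detects perfect confounding", {
  expect_equal(lineage_association_test(
    setNames(rep(1:2, each = 20), paste0("s", 1:40)),
    setNames(rep(c("M1/M2", "M4/M5"), each = 20), paste0("s", 1:40))),
    fisher.test(matrix(c(20, 0, 0, 20), 2))$p.value)
  expect_lt(lineage_association_test(
    setNames(rep(1:2, each = 20), paste0("s", 1:40)),
    setNames(rep(c("M1/M2", "M4/M5"), each = 20), paste0("s", 1:40))), 1e-9)
  lab <- setNames(c(1, 1, 1, 1, 2, 2, 2, 2), paste0("s", 1:8))
  lin <- setNames(c("a", "a", "a", "b", "b", "b", "b", "a"), paste0("s", 1:8))
  expect_equal(lineage_association_test(lab, lin), 34 / 70, tolerance = 1e-12)
  expect_error(lineage_association_test(setNames(rep(1, 8), paste0("s", 1:8)), lin),
               ">= 2 clusters")
})

test_that("gene-count sweep reproduces persistent naive lineage clustering", {
  co <- test_cohort()
  sw <- gene_count_sensitivity(co$log2, co$clinical$fab,
                               counts = c(1000, 1500, 2000))
  expect_true(all(sw$fisher_p < 0.01))
  expect_true(all(sw$K >= 2))
  # counts = all genes runs without error
  sw_all <- gene_count_sensitivity(co$log2, co$clinical$fab,
                                   counts = nrow(co$log2))
  expect_equal(sw_all$n_genes, nrow(co$log2))
  expect_error(gene_count_sensitivity(co$log2, co$clinical$fab,
                                      counts = nrow(co$log2) + 1), "exceeds")
})

test_that("headline decoupling property holds on the shared cohort", {
  co <- test_cohort()
  naive_sel <- variance_filter(co$log2, top_n = 1000)
  hc <- hierarchical_dendrogram(co$log2[naive_sel, ])
  naive <- dynamic_tree_cut(hc)$labels
  res <- decouple_cluster(co$log2, co$clinical$fab)
  ari_nl <- adjusted_rand_index(naive, co$truth$lineage)
  ari_ng <- adjusted_rand_index(naive, co$truth$group)
  ari_dg <- adjusted_rand_index(res$labels, co$truth$group)
  ari_dl <- adjusted_rand_index(res$labels, co$truth$lineage)
  expect_gt(ari_nl, ari_ng)
  expect_gte(ari_dg, 0.8)
  expect_gt(ari_dg, ari_dl)
})
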