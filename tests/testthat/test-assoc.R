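test_that("chi-square: flat table, closed-form 2x2, permutation invariance", {
  flat <- matrix(10, 2, 2)
  res <- chi_square_test(flat)
  expect_equal(res$statistic, 0)
  expect_equal(res$p, 1)

  tab <- matrix(c(12, 5, 7, 15), 2, 2)
  a <- tab[1, 1]; b <- tab[1, 2]; cc <- tab[2, 1]; d <- tab[2, 2]
  n <- sum(tab)
  closed <- n * (a * d - b * cc)^2 /
    (sum(tab[1, ]) * sum(tab[2, ]) * sum(tab[, 1]) * sum(tab[, 2]))
  expect_equal(chi_square_test(tab)$statistic, closed, tolerance = 1e-12)

  big <- matrix(c(16, 16, 16, 15, 13, 5), 2, 3, byrow = TRUE)
  expect_equal(chi_square_test(big)$statistic,
               chi_square_test(big[2:1, c(3, 1, 2)])$statistic)
  expect_error(chi_square_test(matrix(c(0, 0, 1, 2), 2)), "margin")
  expect_warning(chi_square_test(matrix(c(1, 13, 2, 1), 2)), "expected")
})

test_that("Fisher r x c equals full enumeration (point-probability method)", {
  tab <- matrix(c(3, 1, 1, 3), 2)
  expect_equal(fisher_exact_rxc(tab), 34 / 70, tolerance = 1e-12)
  oracle <- enum_fisher(tab)
  expect_equal(oracle$p, 34 / 70, tolerance = 1e-10)

  # random 2x2 and 2x3 tables against enumeration, probabilities sum to 1
  set.seed(21)
  for (i in 1:25) {
    t2 <- matrix(rpois(4, 4) + 1, 2)
    o <- enum_fisher(t2)
    expect_equal(o$total, 1, tolerance = 1e-10)
    expect_equal(fisher_exact_rxc(t2), o$p, tolerance = 1e-9)
  }
  for (i in 1:10) {
    t3 <- matrix(rpois(6, 3) + 1, 2, 3)
    o <- enum_fisher(t3)
    expect_equal(o$total, 1, tolerance = 1e-10)
    expect_equal(fisher_exact_rxc(t3), o$p, tolerance = 1e-9)
  }

  expect_error(fisher_exact_rxc(matrix(200, 2, 2)), "monte_carlo")
  big <- matrix(c(200, 150, 120, 180), 2)
  set.seed(1)
  p_mc <- fisher_exact_rxc(big, monte_carlo = TRUE, B = 20000)
  p_ex <- fisher.test(big)$p.value
  expect_lt(abs(p_mc - p_ex), 0.02)
})

test_that("clinical-characteristics tables reproduce the expected-count rule", {
  ahd <- matrix(c(16, 16, 16, 15, 13, 5), 2, 3, byrow = TRUE)
  res <- contingency_test(ahd)
  expect_equal(res$test, "chisq")
  expect_equal(round(res$p, 2), 0.18)

  vital <- matrix(c(2, 8, 1, 29, 21, 20), 2, 3, byrow = TRUE)
  res2 <- contingency_test(vital)
  expect_equal(res2$test, "fisher")
  expect_equal(round(res2$p, 3), 0.028)
})

test_that("BH adjustment: hand step-up, monotonicity, guards", {
  expect_equal(bh_adjust(c(0.002, 0.01, 0.03, 0.04)),
               c(0.008, 0.02, 0.04, 0.04))
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))   # equal p is a fixed point
  expect_equal(bh_adjust(0.3), 0.3)
  p <- c(0.001, 0.2, 0.8, 0.05)
  q <- bh_adjust(p)
  expect_true(all(q >= p))
  # step-up monotone: sorted q never decreases with sorted p
  expect_true(all(diff(q[order(p)]) >= 0))
  expect_true(all(q <= 1))
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("Wilcoxon rank-sum: exact enumeration case and shift invariance", {
  res <- wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p, 2 / 20)          # 2 of the 20 arrangements are as extreme
  res2 <- wilcoxon_rank_sum(c(1, 2, 3) + 100, c(4, 5, 6) + 100)
  expect_equal(res2$p, res$p)
  expect_error(wilcoxon_rank_sum(numeric(), 1:3), "empty")
})

test_that("Wilcoxon null p-values are roughly uniform", {
  set.seed(22)
  ps <- vapply(1:500, function(i) {
    z <- rnorm(30)
    wilcoxon_rank_sum(z[1:15], z[16:30])$p
  }, 0)
  expect_gte(mean(ps < 0.05), 0.03)
  expect_lte(mean(ps < 0.05), 0.07)
})

test_that("Spearman: monotone extremes and tie-aware brute force", {
  x <- c(1, 3, 4, 7, 9)
  expect_equal(spearman_correlation(x, exp(x))$rho, 1)
  expect_equal(spearman_correlation(x, -x^3)$rho, -1)
  set.seed(23)
  xt <- c(1, 2, 2, 3, 5, 5, 5, 8)
  yt <- c(2, 1, 4, 4, 6, 5, 9, 9)
  got <- spearman_correlation(xt, yt)$rho
  expect_equal(got, cor(rank(xt), rank(yt)), tolerance = 1e-12)
  expect_error(spearman_correlation(rep(1, 5), 1:5), "constant")
  expect_error(spearman_correlation(1:2, 2:3), ">= 3")
})

test_that("mutation analysis: frequency filter, odds ratios, driver recovery", {
  co <- test_cohort()
  labels <- setNames(co$truth$group, colnames(co$mutations))
  ma <- mutation_analysis(co$mutations, labels)
  # <10% frequency rule: a gene mutated in 5/81 samples is excluded
  rare <- rbind(co$mutations,
                RARE = as.integer(seq_len(ncol(co$mutations)) <= 5))
  ma2 <- mutation_analysis(mutation_matrix(rare), labels)
  expect_false("RARE" %in% ma2$cluster_association$gene)
  # planted drivers recovered at q < 0.1
  drivers <- c("ASXL1", "GATA2", "FLT3")
  expect_true(all(drivers %in%
                  ma$cluster_association$gene[ma$cluster_association$significant]))
})

test_that("mutation pair odds ratio equals the cross product", {
  g1 <- c(rep(1L, 12), rep(0L, 12))
  g2 <- c(rep(1L, 10), rep(0L, 2), rep(1L, 3), rep(0L, 9))
  mm <- matrix(c(g1, g2), 2, 24, byrow = TRUE,
               dimnames = list(c("A", "B"), sprintf("s%02d", 1:24)))
  labels <- setNames(rep(1:2, 12), colnames(mm))
  ma <- mutation_analysis(mutation_matrix(mm), labels)
  expect_equal(ma$co_occurrence$odds_ratio, (10 * 9) / (2 * 3))
  expect_false(ma$co_occurrence$zero_cell_corrected)
  # single swap of one gene's coding inverts the OR
  mm2 <- mm; mm2["B", ] <- 1L - mm2["B", ]
  ma2 <- mutation_analysis(mutation_matrix(mm2), labels)
  expect_equal(ma2$co_occurrence$odds_ratio, (2 * 3) / (10 * 9))

  none <- matrix(c(rep(1L, 2), rep(0L, 22)), 1, 24,
                 dimnames = list("Z", colnames(mm)))
  expect_warning(r <- mutation_analysis(mutation_matrix(none), labels),
                 "frequency")
  expect_equal(nrow(r$cluster_association), 0)
})

test_that("RPPA differential: planted shifts up, symmetric shifts split", {
  co <- test_cohort()
  ids3 <- co$clinical$sample_id[co$truth$group == 3]
  ids1 <- co$clinical$sample_id[co$truth$group == 1]
  rp <- rppa_differential(co$proteins, ids3, ids1)
  expect_true(all(c("MTOR.pS2448", "MCL1") %in% rp$protein[rp$up]))
  expect_false(any(rp$down[rp$protein %in% c("MTOR.pS2448", "MCL1")]))

  # exactly symmetric shifts: one protein up, its mirror down
  set.seed(24)
  base <- matrix(rnorm(20 * 40), 20, 40,
                 dimnames = list(sprintf("p%02d", 1:20), sprintf("s%02d", 1:40)))
  grp <- rep(c("A", "B"), each = 20)
  base["p01", grp == "A"] <- base["p01", grp == "A"] + 3
  base["p02", grp == "A"] <- base["p02", grp == "A"] - 3
  rp2 <- rppa_differential(protein_matrix(base), colnames(base)[grp == "A"],
                           colnames(base)[grp == "B"])
  expect_true(rp2$up[rp2$protein == "p01"])
  expect_true(rp2$down[rp2$protein == "p02"])
  expect_error(rppa_differential(co$proteins, ids3[1], ids1), ">= 2")
})

test_that("designated protein pairs share a latent factor (mTOR-axis mirror)", {
  # measured at large n so the generator property, not one cohort's sampling
  # noise, is under test
  set.seed(25)
  mp <- simulate_mutations_proteins(small_config(), sample(1:3, 600, TRUE))
  sp <- spearman_correlation(mp$proteins["MTOR", ],
                             mp$proteins["MTOR.pS2448", ])
  expect_gt(sp$rho, 0.2)
  expect_lt(sp$p, 1e-4)
  sp2 <- spearman_correlation(mp$proteins["MCL1", ], mp$proteins["BAX", ])
  expect_gt(sp2$rho, 0.2)
  # unpaired proteins are uncorrelated by construction
  sp3 <- spearman_correlation(mp$proteins["CASP8", ], mp$proteins["BRAF", ])
  expect_lt(abs(sp3$rho), 0.15)
})
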