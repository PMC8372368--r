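# decoupleAML

Lineage-decoupled transcriptomic classification of acute myeloid leukemia
(AML), with the downstream group characterization that makes the grouping
clinically interpretable: pathway activity, survival, mutations, and protein
(RPPA) differentials.

## The problem and the method

Unsupervised clustering of bulk AML transcriptomes is dominated by
morphologic lineage: patients split along the FAB M1/M2 vs M4/M5 axis, not
along shared disease biology. `decoupleAML` removes that confounder before
clustering:

1. **Lineage screen.** For every gene, log2 normalized expression is
   regressed on FAB indicators (M2, M4, M5 vs the M1 reference) by ordinary
   least squares. P-values are FDR-adjusted per contrast
   (Benjamini–Hochberg), and a gene is *FAB-associated* if any contrast has
   q < 0.05.
2. **Residual clustering.** FAB-associated genes are excluded; the
   remaining genes with log2 variance > 5 feed hierarchical clustering
   (Euclidean distance, complete linkage) with an adaptive (dynamic) tree
   cut and a minimum cluster size. Lineage independence of the resulting
   clusters is tested by Fisher's exact test on the cluster × lineage table.
3. **Characterization.** Clusters are profiled by gene-set tests on DE
   t-statistics, single-sample GSEA (ssGSEA) activity scores compared by
   Wilcoxon rank-sum tests, Kaplan–Meier / log-rank / multivariable Cox
   survival models (univariate screen at p < 0.05, Efron ties, cluster 1
   reference), mutation enrichment and co-occurrence odds ratios (Fisher,
   q < 0.1, <10% frequency filter), and protein differentials
   (Wilcoxon + 75th/25th-percentile difference-in-means rule at q < 0.1).
4. **Transfer.** An up/down signature (|log2FC| > 2, q < 0.05) yields a
   per-sample *group-2-likeness* score, ssGSEA(up) − ssGSEA(down),
   median-split to transfer the grouping to external cohorts.

Because the real cohort data are access-controlled, the package ships a
negative-binomial multi-omic cohort simulator (`simulate_cohort()`) whose
defaults emulate the study conditions: 81 patients, 15,000 genes, a
dominant lineage axis, a hidden 3-level biology grouping (31:29:21) with
planted inflammatory / metabolic / HOX-like gene sets, group-linked
exponential survival, driver mutations (ASXL1 / GATA2 / FLT3 enriched in
one group each) and shifted protein panels — so every stage of the pipeline
can be validated against ground truth.

## Worked example

```r
library(decoupleAML)

co  <- simulate_cohort(sim_config(seed = 1))            # 81 x 15000 cohort
l2  <- log2_transform(normalize_median_of_ratios(co$counts)$normalized)
res <- decouple_cluster(l2, co$clinical$fab)

table(res$labels)                    # cluster sizes 36 / 30 / 15
sum(res$fab_association$fab_associated)  # 671 FAB-associated genes excluded
length(res$selected_genes)           # 165 residual variable genes clustered
res$lineage_p                        # 0.587 - clusters independent of lineage
adjusted_rand_index(res$labels, co$truth$group)  # 1 - latent groups recovered
```

The same cohort clustered naively on the top 1000 variable genes (no
exclusion) splits along lineage with Fisher p = 7.7e-24 — the confounding
the method removes. Downstream, the recovered clusters separate outcomes
(overall-survival log-rank p = 3.7e-5) and the planted "inflammatory" set
scores up while the "HOX-like" set scores down in the protective group
(both q = 1.6e-13 by Wilcoxon on ssGSEA scores), mirroring the biology the
workflow is designed to expose.

A command-line wrapper is included for file-based runs:

```sh
inst/cli/decoupleAML simulate --seed 7 --out-dir cohort/
inst/cli/decoupleAML preprocess --counts cohort/counts.tsv --out-dir run/
inst/cli/decoupleAML decouple-cluster --log2 run/log2.tsv \
    --clinical cohort/clinical.csv --out-dir run/
```

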