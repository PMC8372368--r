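---
title: "Lineage-decoupled classification of AML transcriptomes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Lineage-decoupled classification of AML transcriptomes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(decoupleAML)
```

# The problem

Bulk AML transcriptomes carry a dominant expression axis that tracks
morphologic lineage (FAB M1/M2 granulocytic vs M4/M5 monocytic
differentiation). Clustering patients on raw variable genes therefore
groups them by lineage, masking patient groups that share disease biology
across lineages. The workflow in this package excludes genes whose
expression is explained by FAB class *before* clustering, then asks whether
the residual clusters are (a) independent of lineage and (b) biologically
and clinically meaningful — by pathway activity, survival, mutation and
protein read-outs.

# The core procedure

## Normalization

Raw counts are normalized by median-of-ratios size factors: for sample $j$,
$s_j = \operatorname{median}_g \, c_{gj} / (\prod_k c_{gk})^{1/n}$, the
median taken over genes with a positive count in every sample and computed
on the log-ratio scale (so an even number of reference genes interpolates
geometrically — the convention of standard RNA-seq tools, which we verify
against in the tests). Normalized counts are $\log_2(x + 1)$ transformed.
The pseudocount of 1 is a convention; any positive constant preserves the
rank-based statistics downstream.

## The lineage screen

For each gene, ordinary least squares of log2 expression on indicator
variables for M2, M4 and M5, with M1 the reference:
$y_i = \beta_0 + \beta_2 [M2] + \beta_4 [M4] + \beta_5 [M5] + \varepsilon$.
With dummy coding each $\beta$ is exactly the difference of group means, so
the screen is a per-contrast two-sided t-test with a pooled residual
variance. P-values are BH-adjusted *within each contrast* across genes
(three separate corrections, not one pooled one), and a gene is
FAB-associated when any contrast has $q < 0.05$. Gaussian OLS on log2
values is appropriate here because log2 normalized counts are close to
homoscedastic at this granularity, and because the screen only needs a
well-calibrated ranking, not unbiased effect sizes. No covariates are
adjusted for: the screen deliberately removes *everything* lineage-related,
and any variance shared between lineage and other factors should be
removed with it.

Genes with numerically zero residual variance (constant genes) are
assigned statistic 0 and p = 1 rather than a 0/0 artifact.

## Residual clustering

After exclusion, genes with sample variance > 5 (log2 scale, $n-1$
denominator) are retained. The threshold is the analysis's operating
point for "top variably expressed"; `variance_filter()` also offers a
`top_n` mode used for the naive-clustering sensitivity sweep (1000–3000
genes). Samples are clustered by Euclidean distance and complete linkage.
`stats::hclust` is deterministic given the input order; ties in the
distance matrix are broken by the smallest merge-index pair.

## The dynamic tree cut

The cluster count is not fixed a priori. We cut the dendrogram
adaptively:

1. a static cut at the 0.99 quantile of the merge heights yields initial
   branches;
2. each branch is inspected recursively and **split** when both
   sub-branches have at least `min_cluster_size` (default 8, about 10% of
   an 81-sample cohort) members *and* the merge height exceeds
   `gap_factor` (default 2) times the taller sub-branch — a height-gap
   criterion;
3. branches below the minimum size are merged into the nearest cluster by
   average distance if that distance is within the cut height, otherwise
   left unassigned (label 0);
4. labels are renumbered by decreasing cluster size.

The recursion is the step that needed a design decision. A purely static
quantile cut separates at most the single largest height gap: with three
well-separated groups, the 0.99 quantile interpolates between the two
largest merges and returns only two branches. The height-gap condition
makes the cut adaptive without fragmenting tight clusters: inside a
homogeneous cluster the merge heights grow gradually (ratios near 1), so
the recursion stops, and on two well-separated blobs the result coincides
exactly with a static two-cluster cut — a property the tests assert. Both
parameters are recorded in the provenance output of every run.

## Lineage independence and the sensitivity sweep

Cluster membership vs binary lineage is tested with Fisher's exact test
(point-probability two-sided method) on the $K \times 2$ table, unassigned
samples excluded. The sensitivity sweep repeats naive clustering (no
exclusion) at 1000/1500/2000/2500/3000 top-variance genes to demonstrate
that lineage-driven clustering is not an artifact of one gene count.

# Group characterization

- **Differential expression** is per-gene Welch t on log2 values with BH
  correction, the log2 fold change being the difference of group means.
  The original analysis used a negative-binomial Wald model; we substitute
  Welch t deliberately: every downstream consumer (t-statistic ranking for
  set tests, |log2FC| and q thresholds for signatures) needs only a signed,
  calibrated per-gene statistic, and the Welch form is transparent,
  dependency-free and exactly antisymmetric under group swap (asserted in
  tests). An NB engine could be slotted behind the same interface without
  touching consumers.
- **Set-level tests** compare member-gene statistics against non-member
  statistics with a two-sample t-test, reporting the mean member statistic
  and its direction; BH across sets, significance at q < 0.1.
- **ssGSEA** ranks genes within each sample (descending, ties broken by
  stable gene order) and scores a set as
  $\sum_i [F_{\text{in}}^w(i) - F_{\text{out}}(i)]$, the running weighted
  ECDF of members minus the ECDF of non-members, with weight
  $(\text{rank position}/N)^\alpha$ and $\alpha = 0.25$ by default (the
  convention of the common implementation; exposed as a parameter). At
  $\alpha = 0$ the score is a pure rank statistic, which gives the exact
  invariances the tests exploit (monotone-transform invariance, hand-
  enumerable closed forms). Scores are *not* min–max normalized across
  samples by default: all downstream uses (Wilcoxon comparisons, median
  splits) are invariant to that normalization.
- **Pathway activity comparisons** are Wilcoxon rank-sum per set with BH
  across sets at q < 0.05; direction is the median difference.
- **Survival**: Kaplan–Meier product-limit curves (median survival =
  smallest time with $S \le 0.5$, reported as undefined when the curve
  never crosses 0.5 — not as the maximum time); unweighted log-rank with
  $K-1$ df; Cox partial likelihood with Efron tie handling (Breslow by
  flag). The multivariable workflow screens clinical variables by
  univariate Cox at p < 0.05 (listwise deletion per variable, failed fits
  skipped with a warning) and then fits cluster indicators with cluster 1
  as reference plus the screened variables. Monotone likelihood (perfect
  separation) is raised as an error rather than returning a divergent
  coefficient.
- **Mutations**: genes mutated in <10% of samples are excluded; per-gene
  Fisher on the mutation × cluster table, BH, q < 0.1; pairwise 2×2 Fisher
  with the cross-product odds ratio. A Haldane 0.5 correction is applied
  to the OR only when a cell is zero, and the output flags when it was.
- **Proteins**: per-protein difference in means with a Wilcoxon p, BH;
  up/down calls require both q < 0.1 and the difference beyond the
  75th/25th percentile of the per-comparison difference vector. The
  percentile thresholds are computed over the proteins of the given
  comparison (the natural reading of the rule; noted because it is the one
  place the published description is ambiguous).
- **Group-2-likeness**: ssGSEA(up) − ssGSEA(down) per sample, median split
  with ties and, for odd n, the median sample going to the high stratum.
  Strata are computed within each cohort being scored, not carried over
  from the discovery cohort, matching the stated per-cohort stratification.

# The synthetic cohort generator

`sim_config()` defaults define the study conditions and are not tuned per
analysis:

| parameter | default | rationale |
|---|---|---|
| `n_samples` | 81 | cohort size of the study design |
| `latent_group_probs` | 31:29:21 | published group sizes |
| `lineage_frac_m45` | 45/81 | published FAB split |
| `n_genes` | 15,000 | expressed-gene scale |
| `n_lineage_genes` / `n_biology_genes` | 600 / 300 | disjoint planted axes |
| effect sizes | 5 (log2) | strong planted shifts; chosen once so that naive clustering reproduces the lineage-confounding phenomenon and planted biology genes clear the variance-5 selection ($\delta^2 p(1-p) > 5$); no published effect sizes exist to match |
| `nb_dispersion` | 0.2 | typical bulk RNA-seq overdispersion; counts are NB with variance $\mu + \alpha\mu^2$ (verified by a moment check) |
| survival baselines | medians ≈ 25 / 22 / 42 weeks | published overall medians for OS / EFS / remission duration |
| `hazard_multipliers` | (1, 0.5, 1) | protective middle group |
| `censoring_rate` | 0.005/week | ≈ 14% censored, matching 11/81 alive |
| driver rates | 0.6 in-group vs 0.1 out | detectable at n = 81 with ≥80% power at q < 0.1 |
| `protein_shift` | 1.5 | group-3 shift on the mTOR-axis pairs |

Biology genes are assigned to groups in a fixed rotation with 80% shifted
up and 20% down, so the planted "inflammatory" (up in group 2),
"metabolic" (up in group 3) and "HOX-like" (down in group 2) sets always
have a pool to draw from; decoy sets of matched sizes are drawn from the
whole gene universe. FAB labels are generated as the binary lineage and
then refined to a balanced random M1/M2 or M4/M5 split, because the
screen's regression interface needs four levels while the confounding
structure is two-level.

What the generator does **not** emulate: gene–gene correlation beyond the
planted block structure, batch effects, library-size extremes, realistic
mutation co-occurrence networks, informative censoring, or any coupling
between covariates and the latent groups (covariates are independent by
design so that outcome differences are group-driven). Passing tests on
synthetic cohorts therefore demonstrate that the *pipeline* recovers the
structure it assumes, not that real AML cohorts contain exactly this
structure.

# Numerical and testing choices

- Exponential (not Weibull) survival: the analysis consumes only
  (time, event) pairs and Cox is semi-parametric, so the extra shape
  parameter buys nothing for validation.
- Fisher's exact test delegates to the standard network-algorithm
  implementation; the test suite holds it to a full hypergeometric
  enumeration oracle (probabilities summing to 1, point-probability
  two-sided p) on small tables, and large tables require an explicit
  seeded Monte Carlo flag.
- Clinical-characteristics tables use the expected-count rule: Fisher
  exact when any expected cell is below 5, otherwise Pearson chi-square
  without continuity correction; continuous variables use Kruskal–Wallis.
- BH adjustment is the standard step-up; note it is *not* idempotent on
  arbitrary already-adjusted vectors (only degenerate cases such as
  all-equal vectors are fixed points), so the tests assert the true
  step-up properties instead.
- Cox convergence and tie handling follow the survival package; the
  two-group log-rank statistic is cross-checked against the Cox-Breslow
  score test to 1e-8.
- Problem sizes in the test suite: most tests run on a shared 3000-gene,
  81-sample cohort with planted counts scaled proportionally; the
  decoupling-recovery check runs ten full 81 × 15,000 cohorts; calibration
  checks use 500 null replicates; ARI is computed with the standard
  chance-corrected form. These sizes were chosen to exercise every code
  path at full cohort width while keeping the suite fast enough to run on
  every change.

# Known limitations

- The FAB screen removes any biology that is genuinely collinear with
  lineage; a latent group expressed only through lineage-associated genes
  is invisible to this design by construction.
- The dynamic tree cut implements the simple tree variant with a height-gap
  rule; the hybrid variant (shape-based cluster criteria) is out of scope,
  and very unbalanced or nested cluster geometries may be merged or left
  unassigned.
- Welch-t DE does not model counts; at very low expression the log2
  transform compresses effects, so signature log2FC thresholds are
  conservative there.
- The univariate-then-multivariable Cox screen inherits the usual caveats
  of screening on the same data used for the final model; it mirrors the
  published workflow rather than a modern selection procedure.
- Microarray validation cohorts are consumed as pre-exported matrices with
  opaque row identifiers; mapping probes to gene symbols is the caller's
  responsibility.
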