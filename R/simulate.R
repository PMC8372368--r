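#' Simulation configuration for synthetic AML cohorts
#'
#' Builds the parameter list for [simulate_cohort()]. Defaults emulate the
#' structure of an 81-patient newly diagnosed AML cohort whose dominant
#' transcriptomic axis tracks morphologic lineage (M1/M2 vs M4/M5) and whose
#' secondary axis tracks a hidden 3-level biology grouping (sized 31:29:21)
#' that drives outcomes, mutations and protein shifts.
#'
#' Counts are negative binomial with per-gene log2 baseline means drawn from
#' N(baseline_log2_mean, baseline_log2_sd) and a single dispersion. Planted
#' lineage genes are shifted (log2 scale) in M4/M5 samples; planted biology
#' genes are shifted up or down in their assigned latent group. Survival is
#' exponential with per-group hazard multipliers, a log-linear age effect and
#' independent exponential censoring; event times are in weeks, with
#' baselines matched to overall medians of roughly 25, 22 and 42 weeks for
#' OS, EFS and remission duration. Three driver mutations are enriched in
#' one group each; four designated proteins are shifted in group 3.
#'
#' @param n_samples,n_genes cohort dimensions.
#' @param lineage_frac_m45 probability a sample is M4/M5 lineage.
#' @param latent_group_probs probabilities of latent groups 1..3; must sum to 1.
#' @param n_lineage_genes,n_biology_genes planted gene counts (disjoint).
#' @param lineage_effect_size,biology_effect_size log2-scale shifts (>= 0).
#' @param nb_dispersion negative-binomial dispersion alpha (> 0); variance
#'   mu + alpha mu^2.
#' @param baseline_log2_mean,baseline_log2_sd baseline log2-mean distribution.
#' @param hazard_multipliers per-group hazard multipliers (length 3, > 0).
#' @param os_base_hazard,efs_base_hazard,remdur_base_hazard baseline hazards
#'   per week.
#' @param censoring_rate exponential censoring rate per week (0 = none).
#' @param age_hazard log hazard ratio per year of age (centered at 64).
#' @param driver_rate,driver_baseline_rate driver mutation probability inside /
#'   outside its enriched group.
#' @param passenger_rate mutation probability for non-driver genes.
#' @param protein_shift group-3 mean shift for the designated proteins.
#' @param set_sizes sizes of the planted inflammatory / metabolic / HOX-like
#'   gene sets.
#' @param n_decoy_sets number of size-matched random decoy sets.
#' @param seed integer RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_samples = 81, n_genes = 15000,
                       lineage_frac_m45 = 45 / 81,
                       latent_group_probs = c(31, 29, 21) / 81,
                       n_lineage_genes = 600, n_biology_genes = 300,
                       lineage_effect_size = 5, biology_effect_size = 5,
                       nb_dispersion = 0.2,
                       baseline_log2_mean = 4, baseline_log2_sd = 2,
                       hazard_multipliers = c(1, 0.5, 1),
                       os_base_hazard = log(2) / 25.4,
                       efs_base_hazard = log(2) / 22.4,
                       remdur_base_hazard = log(2) / 42.4,
                       censoring_rate = 0.005,
                       age_hazard = 0.02,
                       driver_rate = 0.6, driver_baseline_rate = 0.1,
                       passenger_rate = 0.15,
                       protein_shift = 1.5,
                       set_sizes = c(inflammatory = 30, metabolic = 30,
                                     hox_like = 20),
                       n_decoy_sets = 20,
                       seed = 1) {
  cfg <- as.list(environment())
  # tolerate list-valued vectors from YAML configs
  for (f in c("latent_group_probs", "hazard_multipliers", "set_sizes"))
    cfg[[f]] <- unlist(cfg[[f]])
  latent_group_probs <- cfg$latent_group_probs
  hazard_multipliers <- cfg$hazard_multipliers
  if (abs(sum(latent_group_probs) - 1) > 1e-8)
    stop("latent_group_probs must sum to 1")
  if (lineage_effect_size < 0 || biology_effect_size < 0)
    stop("effect sizes must be >= 0")
  if (n_lineage_genes + n_biology_genes > n_genes)
    stop("n_lineage_genes + n_biology_genes must be <= n_genes")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (any(hazard_multipliers <= 0) || os_base_hazard <= 0 ||
      efs_base_hazard <= 0 || remdur_base_hazard <= 0)
    stop("hazards and multipliers must be > 0")
  if (censoring_rate < 0) stop("censoring_rate must be >= 0")
  for (r in c(driver_rate, driver_baseline_rate, passenger_rate))
    if (r < 0 || r > 1) stop("mutation rates must lie in [0, 1]")
  class(cfg) <- "sim_config"
  cfg
}

# deterministic gene truth layout given a config: which genes carry lineage or
# biology effects, the biology gene's group and direction (80% up, 20% down
# within each group). Gene positions are randomized by the caller's RNG.
plant_gene_truth <- function(cfg) {
  gene_ids <- sprintf("G%05d", seq_len(cfg$n_genes))
  planted <- sample.int(cfg$n_genes, cfg$n_lineage_genes + cfg$n_biology_genes)
  lin_idx <- planted[seq_len(cfg$n_lineage_genes)]
  bio_idx <- planted[-seq_len(cfg$n_lineage_genes)]
  bio_group <- rep_len(1:3, cfg$n_biology_genes)
  bio_dir <- integer(cfg$n_biology_genes)
  for (g in 1:3) {
    k <- which(bio_group == g)
    n_dn <- floor(length(k) * 0.2)
    bio_dir[k] <- c(rep(1L, length(k) - n_dn), rep(-1L, n_dn))
  }
  truth <- data.frame(gene_id = gene_ids,
                      lineage_gene = FALSE, biology_gene = FALSE,
                      biology_group = NA_integer_, biology_direction = NA_integer_)
  truth$lineage_gene[lin_idx] <- TRUE
  truth$biology_gene[bio_idx] <- TRUE
  truth$biology_group[bio_idx] <- bio_group
  truth$biology_direction[bio_idx] <- bio_dir
  truth
}

#' Simulate the expression layer of a synthetic cohort
#'
#' Draws lineage and latent-group labels, then negative-binomial counts with
#' log2 mean = baseline + lineage shift (planted lineage genes, M4/M5
#' samples) + signed biology shift (planted biology genes, samples of the
#' gene's group). Uses the current RNG state; seed via [simulate_cohort()]
#' or `set.seed()`.
#'
#' @param config a [sim_config()].
#' @return list with `counts` (raw-count [expression_matrix()]), `lineage`
#'   (0 = M1/M2, 1 = M4/M5), `group` (latent 1..3), `gene_truth` data frame.
#' @export
simulate_expression <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  n <- config$n_samples; G <- config$n_genes
  sample_ids <- sprintf("S%03d", seq_len(n))
  lineage <- stats::rbinom(n, 1, config$lineage_frac_m45)
  group <- sample.int(3, n, replace = TRUE, prob = config$latent_group_probs)
  truth <- plant_gene_truth(config)
  log2mu <- matrix(stats::rnorm(G, config$baseline_log2_mean,
                                config$baseline_log2_sd), G, n)
  log2mu[log2mu < 0] <- 0
  lin <- truth$lineage_gene
  log2mu[lin, lineage == 1] <- log2mu[lin, lineage == 1] + config$lineage_effect_size
  for (g in 1:3) {
    k <- which(truth$biology_gene & truth$biology_group == g)
    if (length(k))
      log2mu[k, group == g] <- log2mu[k, group == g] +
        config$biology_effect_size * truth$biology_direction[k]
  }
  log2mu[log2mu < 0] <- 0
  counts <- matrix(stats::rnbinom(G * n, mu = 2^log2mu,
                                  size = 1 / config$nb_dispersion), G, n,
                   dimnames = list(truth$gene_id, sample_ids))
  list(counts = expression_matrix(counts, "raw_counts"),
       lineage = lineage, group = group, gene_truth = truth)
}

# balanced random refinement of a binary lineage into 4 FAB labels
refine_fab <- function(lineage) {
  fab <- character(length(lineage))
  for (lv in 0:1) {
    k <- which(lineage == lv)
    labs <- if (lv == 0) c("M1", "M2") else c("M4", "M5")
    fab[k] <- sample(rep_len(labs, length(k)))
  }
  fab
}

#' Simulate the clinical/survival layer
#'
#' FAB labels are drawn consistent with the expression lineage factor
#' (binary lineage refined to a balanced random M1/M2 or M4/M5 split).
#' Demographic covariates are drawn independently of the latent group so
#' that outcome differences are group-driven. OS, EFS and remission-duration
#' times are exponential with hazard
#' `h0 * multiplier(group) * exp(age_hazard * (age - 64))` and independent
#' exponential censoring; times in weeks.
#'
#' @param config a [sim_config()].
#' @param group latent group labels (1..3).
#' @param lineage binary lineage (0 = M1/M2, 1 = M4/M5).
#' @return a [clinical_table()].
#' @export
simulate_clinical_survival <- function(config, group, lineage) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(group)
  stopifnot(length(lineage) == n)
  age <- pmin(pmax(stats::rnorm(n, 64.3, 14.1), 18), 90)
  df <- data.frame(
    sample_id = sprintf("S%03d", seq_len(n)),
    fab = refine_fab(lineage),
    eln = sample(c("favorable", "intermediate", "unfavorable"), n, TRUE,
                 prob = c(5, 46, 30) / 81),
    age = round(age, 1),
    sex = sample(c("female", "male"), n, TRUE, prob = c(34, 47) / 81),
    ahd = stats::runif(n) < 33 / 81,
    treatment = ifelse(stats::runif(n) < 11 / 81, NA,
                       sample(c("arac", "hma", "investigational"), n, TRUE,
                              prob = c(56, 9, 5) / 70)),
    blast_pct = round(pmin(pmax(stats::rnorm(n, 60, 23.1), 1), 100), 1),
    stringsAsFactors = FALSE)
  lin_mult <- config$hazard_multipliers[group] *
    exp(config$age_hazard * (age - 64))
  for (ep in c("os", "efs", "remdur")) {
    h0 <- config[[paste0(ep, "_base_hazard")]]
    tt <- stats::rexp(n, h0 * lin_mult)
    cens <- if (config$censoring_rate > 0)
      stats::rexp(n, config$censoring_rate) else rep(Inf, n)
    df[[paste0(ep, "_time")]] <- round(pmin(tt, cens), 2)
    df[[paste0(ep, "_event")]] <- as.integer(tt <= cens)
  }
  clinical_table(df)
}

#' Simulate mutation and protein layers
#'
#' Three driver genes (ASXL1, GATA2, FLT3) carry an elevated Bernoulli
#' mutation rate in latent groups 1, 2 and 3 respectively; the remaining
#' panel genes mutate at a flat passenger rate. Proteins are standard normal
#' with two correlated pairs (MTOR / MTOR.pS2448 and MCL1 / BAX) shifted
#' upward in group 3.
#'
#' @param config a [sim_config()].
#' @param group latent group labels (1..3).
#' @return list with `mutations` ([mutation_matrix()]) and `proteins`
#'   ([protein_matrix()]).
#' @export
simulate_mutations_proteins <- function(config, group) {
  stopifnot(inherits(config, "sim_config"))
  n <- length(group)
  sample_ids <- sprintf("S%03d", seq_len(n))
  drivers <- c(ASXL1 = 1L, GATA2 = 2L, FLT3 = 3L)
  passengers <- c("TET2", "NPM1", "NRAS", "DNMT3A", "IDH1", "IDH2", "TP53",
                  "RUNX1", "CEBPA", "KIT", "KRAS", "WT1", "SRSF2", "SF3B1",
                  "U2AF1", "EZH2", "STAG2")
  genes <- c(names(drivers), passengers)
  calls <- matrix(0L, length(genes), n, dimnames = list(genes, sample_ids))
  for (g in names(drivers)) {
    rate <- ifelse(group == drivers[[g]], config$driver_rate,
                   config$driver_baseline_rate)
    calls[g, ] <- stats::rbinom(n, 1, rate)
  }
  for (g in passengers)
    calls[g, ] <- stats::rbinom(n, 1, config$passenger_rate)

  shifted_pairs <- list(c("MTOR", "MTOR.pS2448"), c("MCL1", "BAX"))
  others <- c("CASP8", "BAK1", "BRAF", "MAPK9", "CTNNB1", "BAD.pS155",
              "CASP3.cl175", "MAP2K1.pS217", "AKT1", "AKT1.pS473",
              "RPS6.pS235", "RPS6.pS240", "TP53.prot", "STAT3", "STAT3.pY705",
              "JAK2", "GSK3B", "PTEN", "ERBB2", "SRC", "FOXO3", "RB1",
              "CCND1", "MYC", "BCL2", "BCL2L1")
  prots <- c(unlist(shifted_pairs), others)
  vals <- matrix(stats::rnorm(length(prots) * n), length(prots), n,
                 dimnames = list(prots, sample_ids))
  for (pair in shifted_pairs) {
    z <- stats::rnorm(n)                       # shared factor within a pair
    for (p in pair)
      vals[p, ] <- 0.6 * z + 0.8 * stats::rnorm(n) +
        config$protein_shift * (group == 3)
  }
  list(mutations = mutation_matrix(calls), proteins = protein_matrix(vals))
}

#' Generate the planted gene-set collection
#'
#' Emits an "inflammatory" set (genes up in group 2), a "metabolic" set
#' (up in group 3), a "HOX-like" set (down in group 2), and size-matched
#' random decoy sets drawn from the whole gene universe.
#'
#' @param config a [sim_config()].
#' @param gene_truth the `gene_truth` data frame from [simulate_expression()].
#' @return a [gene_set_collection()].
#' @export
generate_gene_set_collection <- function(config, gene_truth) {
  stopifnot(inherits(config, "sim_config"))
  pick <- function(group, dir, size, label) {
    pool <- gene_truth$gene_id[gene_truth$biology_gene &
                               gene_truth$biology_group == group &
                               gene_truth$biology_direction == dir]
    if (size > length(pool))
      stop(sprintf("requested %s set size %d exceeds available genes (%d)",
                   label, size, length(pool)))
    sample(pool, size)
  }
  sz <- config$set_sizes
  sets <- list(inflammatory = pick(2, 1, sz[["inflammatory"]], "inflammatory"),
               metabolic = pick(3, 1, sz[["metabolic"]], "metabolic"),
               hox_like = pick(2, -1, sz[["hox_like"]], "hox_like"))
  if (config$n_decoy_sets > 0) {
    decoy_sizes <- rep_len(sz, config$n_decoy_sets)
    for (i in seq_len(config$n_decoy_sets)) {
      if (decoy_sizes[i] > nrow(gene_truth))
        stop("requested decoy set size exceeds gene universe")
      sets[[sprintf("decoy_%02d", i)]] <-
        sample(gene_truth$gene_id, decoy_sizes[i])
    }
  }
  gene_set_collection(sets)
}

#' Simulate a complete multi-omic cohort
#'
#' Seeds the RNG from `config$seed` and generates every layer: raw counts,
#' clinical table with survival endpoints, binary mutation panel, protein
#' panel, planted gene sets, and the ground-truth labels. Fixed seed gives a
#' byte-identical cohort.
#'
#' @param config a [sim_config()].
#' @return list of class `synthetic_cohort` with elements `counts`,
#'   `clinical`, `mutations`, `proteins`, `gene_sets`, `truth` (list with
#'   `group`, `lineage`, `gene_truth`) and `config`.
#' @export
simulate_cohort <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  ex <- simulate_expression(config)
  clin <- simulate_clinical_survival(config, ex$group, ex$lineage)
  mp <- simulate_mutations_proteins(config, ex$group)
  gs <- generate_gene_set_collection(config, ex$gene_truth)
  out <- list(counts = ex$counts, clinical = clin,
              mutations = mp$mutations, proteins = mp$proteins,
              gene_sets = gs,
              truth = list(group = ex$group, lineage = ex$lineage,
                           gene_truth = ex$gene_truth),
              config = config)
  class(out) <- "synthetic_cohort"
  out
}

#' Write a synthetic cohort to disk
#'
#' Writes counts.tsv, clinical.csv, mutations.tsv, proteins.tsv,
#' gene_sets.gmt, truth_samples.tsv and truth_genes.tsv into `dir`.
#'
#' @param cohort a `synthetic_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_expression_matrix(cohort$counts, file.path(dir, "counts.tsv"))
  write_clinical_table(cohort$clinical, file.path(dir, "clinical.csv"))
  wr <- function(m, f) utils::write.table(
    data.frame(id = rownames(m), m, check.names = FALSE),
    file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  wr(cohort$mutations, "mutations.tsv")
  wr(round(cohort$proteins, 6), "proteins.tsv")
  write_gene_sets_gmt(cohort$gene_sets, file.path(dir, "gene_sets.gmt"))
  utils::write.table(
    data.frame(sample_id = colnames(cohort$counts),
               latent_group = cohort$truth$group,
               lineage = ifelse(cohort$truth$lineage == 1, "M4/M5", "M1/M2")),
    file.path(dir, "truth_samples.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  utils::write.table(cohort$truth$gene_truth,
                     file.path(dir, "truth_genes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
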