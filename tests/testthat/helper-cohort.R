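# Shared small synthetic cohort (3000 genes) so most tests avoid repeating
# the simulation; built lazily and cached for the whole run.

small_config <- function(seed = 1, ...) {
  defaults <- list(n_genes = 3000, n_lineage_genes = 200,
                   n_biology_genes = 150,
                   set_sizes = c(inflammatory = 15, metabolic = 15,
                                 hox_like = 8),
                   n_decoy_sets = 10, seed = seed)
  do.call(sim_config, utils::modifyList(defaults, list(...)))
}

.cohort_cache <- new.env(parent = emptyenv())

test_cohort <- function() {
  if (is.null(.cohort_cache$co)) {
    co <- simulate_cohort(small_config())
    co$log2 <- log2_transform(normalize_median_of_ratios(co$counts)$normalized)
    .cohort_cache$co <- co
  }
  .cohort_cache$co
}
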