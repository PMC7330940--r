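# Shared small cohorts, built once per test run.

.cohort_cache <- new.env(parent = emptyenv())

cached_cohort <- function(name, cfg) {
  got <- .cohort_cache[[name]]
  if (is.null(got)) {
    got <- simulate_cohort(cfg)
    .cohort_cache[[name]] <- got
  }
  got
}

# default-conditions cohort, scaled to test size
small_cohort <- function() {
  cached_cohort("small", sim_config(n_genes = 25, seed = 42))
}

# error-free cohort for exact truth-recovery checks
clean_cohort <- function() {
  cached_cohort("clean", sim_config(n_genes = 20, seed = 101,
                                    error_rate = 0))
}

clean_snps <- function() {
  got <- .cohort_cache[["clean_snps"]]
  if (is.null(got)) {
    co <- clean_cohort()
    got <- call_species_snps(co$coord_maps, co$parent_pileups)
    .cohort_cache[["clean_snps"]] <- got
  }
  got
}
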