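# Shared fixtures, built once per test run.

.fixture_env <- new.env(parent = emptyenv())

# the default synthetic bundle (seed-fixed); ~2 s to build
default_bundle <- function() {
  if (is.null(.fixture_env$bundle)) {
    .fixture_env$bundle <- simulate_study(sim_config(seed = 1L))
  }
  .fixture_env$bundle
}

# a scaled-down configuration for multi-seed property tests
small_config <- function(seed) {
  sim_config(seed = seed, n_chromosomes = 4L, chrom_length = 100000L,
             n_coding = 30L, n_noncoding = 30L, n_specific = 3L,
             n_de_pairs = 3L, n_coexpr_pairs = 3L, n_cp_coexpr = 1L,
             n_mt_coexpr = 1L, n_mirnas = 4L, n_target_sites = 3L,
             n_precursor_embeddings = 2L, n_etm_sites = 2L,
             n_organelle_homology = 1L, n_chloroplast_cds = 3L,
             n_mitochondrial_cds = 3L)
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
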