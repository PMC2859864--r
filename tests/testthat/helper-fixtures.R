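# Shared fixtures, built once per test run and cached. The large run
# (200 genes, seed 1, generator defaults) backs the truth-recovery and
# conservation checks; the small fixtures back the unit tests.

.fx <- new.env(parent = emptyenv())

# 12 genes, no isoforms/artifacts: mapping and annotation unit tests
fx_small <- function() {
  if (is.null(.fx$small)) {
    cfg <- sim_config(seed = 11, n_genes = 12, chimera_rate = 0,
                      ncrna_rate = 0, pathogen_rate = 0,
                      isoform_rates = c(retained_intron = 0, alt_donor = 0,
                                        alt_acceptor = 0, exon_skip = 0))
    sim <- simulate_genome(cfg)
    tx <- simulate_transcripts(sim, cfg$isoform_rates, seed = 12)
    .fx$small <- list(cfg = cfg, sim = sim, tx = tx,
                      dbs = sim_reference_dbs(sim))
  }
  .fx$small
}

# 10 genes, redundancy 3, no contaminants: clustering unit tests
fx_cluster <- function() {
  if (is.null(.fx$cluster)) {
    cfg <- sim_config(seed = 21, n_genes = 10, chimera_rate = 0,
                      ncrna_rate = 0, pathogen_rate = 0, redundancy_mean = 3,
                      isoform_rates = c(retained_intron = 0, alt_donor = 0,
                                        alt_acceptor = 0, exon_skip = 0))
    sim <- simulate_genome(cfg)
    tx <- simulate_transcripts(sim, cfg$isoform_rates, seed = 22)
    lib <- simulate_clone_library(tx, cfg, sim, seed = 23)
    .fx$cluster <- list(cfg = cfg, sim = sim, tx = tx, lib = lib)
  }
  .fx$cluster
}

# the full noiseless study: 200 genes, seed 1, generator defaults
fx_study <- function() {
  if (is.null(.fx$study)) {
    cfg <- sim_config(seed = 1, n_genes = 200)
    .fx$study <- run_pipeline(cfg, outdir = NULL, run_preprocess = FALSE,
                              run_mapping = TRUE, run_snp = FALSE)
    .fx$study$cfg <- cfg
  }
  .fx$study
}
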