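# small shared fixtures, all built in code

# a 4-drug x 3-target network with 6 associations
edge_fixture_lines <- function() {
  c("d1\tt1", "d2\tt1", "d3\tt2", "d4\tt2", "d1\tt3", "d4\tt3")
}

write_edge_fixture <- function(lines = edge_fixture_lines()) {
  path <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

# deterministic tiny latent matrix with one tight cluster
tight_cluster_latent <- function(n = 20, n_tight = 5, d = 3, seed = 7,
                                 spread = 4) {
  set.seed(seed)
  U <- matrix(runif(n * d, 0, spread), n, d)
  U[seq_len(n_tight), ] <- rep(c(1, 1, 1), each = n_tight) +
    matrix(rnorm(n_tight * d, 0, 0.02), n_tight, d)
  rownames(U) <- sprintf("d%02d", seq_len(n))
  U
}

# fast PMF settings for fixture-scale fits
fast_pmf <- function(seed = 1L) {
  pmf_config(latent_dim = 8L, max_iter = 200L, seed = seed)
}

scenario_pipeline_config <- function(sc, seed, n_runs = 30L, ...) {
  pipeline_config(
    interactions = sc$R, target_id = sc$target_id, metadata = sc$metadata,
    molecules = sc$descriptors,
    pmf = pmf_config(latent_dim = 8L, max_iter = 200L),
    ensemble = ensemble_config(n_runs = n_runs, k = 10L, freq_threshold = 0.2),
    similarity = sc$sim_config, seed = seed, ...)
}
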