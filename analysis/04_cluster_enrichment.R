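#!/usr/bin/env Rscript
# Cluster the pooled drug set's latent vectors under three distance
# metrics, test every tree node for known-ligand enrichment, and intersect
# the enriched-cluster members across metrics.

suppressMessages(library(pmfrepurpose))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sc <- make_planted_scenario(seed = seed)
ens <- ensemble_config(n_runs = 30, k = 10, seed_base = seed + 10000L,
                       freq_threshold = 0.2)
pmfc <- pmf_config(latent_dim = 8, max_iter = 200)
tab <- run_ensemble(sc$R, pmfc, ens, sc$target_id, known_set = sc$known_ids)
cand <- select_candidates(tab)
combined <- combine_candidate_set(sc$approved_known_ids, cand)
message(sprintf("clustering universe: %d approved knowns + %d candidates = %d drugs",
                length(sc$approved_known_ids), length(cand), length(combined)))

# consensus latent geometry: average pairwise distances over 5 seeded fits
fits <- lapply(1:5, function(f) {
  pmf_fit(sc$R, pmf_config(latent_dim = 8, max_iter = 200,
                           seed = seed + 20000L + f - 1L))$U[combined, , drop = FALSE]
})

per_metric <- list()
for (metric in c("euclidean", "cosine", "cityblock")) {
  D <- Reduce(`+`, lapply(fits, pairwise_distance, metric = metric)) / length(fits)
  dend <- agglomerate(D, linkage = "average", metric = metric)
  write_newick(dend, file.path(out, sprintf("dendrogram_%s.nwk", metric)))
  enr <- enriched_clusters(dend, sc$approved_known_ids, alpha = 0.05, min_size = 3)
  write_enrichment(enr, file.path(out, sprintf("enrichment_%s.csv", metric)))
  per_metric[[metric]] <- enriched_members(enr)
  message(sprintf("  %-9s: %d enriched cluster(s), %d member drugs",
                  metric, nrow(enr), length(per_metric[[metric]])))
}

consensus <- consensus_hits(per_metric, cand)
writeLines(consensus, file.path(out, "consensus_hits.txt"))
message(sprintf("consensus across metrics: %d candidate drug(s): %s",
                length(consensus), paste(consensus, collapse = ", ")))
message(sprintf("  planted hidden drugs recovered: %d / %d",
                sum(sc$hidden_ids %in% consensus), length(sc$hidden_ids)))
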