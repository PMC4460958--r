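#!/usr/bin/env Rscript
# Expand a chemical reference panel around the approved known ligands and
# keep the consensus hits whose best two-component combo score against the
# panel reaches the 1.5 threshold.

suppressMessages(library(pmfrepurpose))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

sc <- make_planted_scenario(seed = seed)
consensus_file <- file.path(out, "consensus_hits.txt")
if (!file.exists(consensus_file)) {
  stop("run analysis/04_cluster_enrichment.R first: ", consensus_file,
       " is missing")
}
consensus <- readLines(consensus_file)
message(sprintf("filtering %d consensus hit(s) by chemical similarity ...",
                length(consensus)))

known_desc <- sc$descriptors[sc$approved_known_ids]
reference <- expand_reference(known_desc, sc$descriptors, threshold = 1.5)
message(sprintf("  reference panel around knowns: %d drugs", length(reference)))

final <- similarity_filter(consensus, sc$descriptors, reference, sc$sim_config)
write.csv(final, file.path(out, "final_hits.csv"), row.names = FALSE)
message(sprintf("  %d hit(s) pass the combo threshold %.1f:",
                nrow(final), sc$sim_config$combo_threshold))
for (i in seq_len(nrow(final))) {
  role <- if (final$drug_id[i] %in% sc$hidden_ids) "planted hidden" else "other"
  message(sprintf("    %d. %s  combo %.3f  (%s)", i, final$drug_id[i],
                  final$score[i], role))
}
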