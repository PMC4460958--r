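#!/usr/bin/env Rscript
# Generate the planted study inputs: a low-rank drug-target network with
# withheld true associations, a fingerprint library with similarity
# families, and the coupled end-to-end scenario whose files the later
# stages consume.

suppressMessages(library(pmfrepurpose))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out <- "results/data"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

message("planted drug-target network (200 x 50, rank 5, 5% density) ...")
planted <- make_planted_dti(n = 200, m = 50, D_true = 5, density = 0.05,
                            n_hidden = 20, seed = seed)
write_interactions(planted$R, file.path(out, "planted_interactions.tsv"))
write.csv(planted$hidden, file.path(out, "planted_hidden_pairs.csv"),
          row.names = FALSE)
message(sprintf("  %d training associations, %d withheld as hidden positives",
                nrow(planted$R$pairs), nrow(planted$hidden)))

message("planted fingerprint library (60 molecules, 4 families) ...")
lib <- make_drug_library(n_molecules = 60, n_families = 4, seed = seed)
write_molecules(lib$descriptors, file.path(out, "library_molecules.txt"))
write.csv(data.frame(drug_id = names(lib$families), family = lib$families),
          file.path(out, "library_families.csv"), row.names = FALSE)

message("coupled end-to-end scenario (latent + fingerprint family) ...")
sc <- make_planted_scenario(seed = seed)
paths <- write_scenario(sc, out)
truth <- data.frame(
  drug_id = sc$R$drugs,
  role = ifelse(sc$R$drugs %in% sc$hidden_ids, "hidden",
         ifelse(sc$R$drugs %in% sc$known_ids, "known",
         ifelse(sc$R$drugs %in% sc$decoy_ids, "decoy", "background"))))
write.csv(truth, file.path(out, "scenario_truth.csv"), row.names = FALSE)
message(sprintf("  query target %s: %d known ligands (%d approved), %d hidden, %d decoys",
                sc$target_id, length(sc$known_ids),
                length(sc$approved_known_ids), length(sc$hidden_ids),
                length(sc$decoy_ids)))
message("inputs written under ", out)
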