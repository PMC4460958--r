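#!/usr/bin/env Rscript
# Fit a single probabilistic matrix factorization model to the planted
# network from 01_simulate.R and measure how well it ranks the withheld
# associations above sampled negatives.

suppressMessages(library(pmfrepurpose))

args <- commandArgs(trailingOnly = TRUE)
seed <- if (length(args)) as.integer(args[[1]]) else 1L
out <- "results"
dir.create(out, showWarnings = FALSE, recursive = TRUE)

planted <- make_planted_dti(n = 200, m = 50, D_true = 5, density = 0.05,
                            n_hidden = 20, seed = seed)
cfg <- pmf_config(seed = seed + 1L)
message(sprintf("fitting PMF: D = %d, reg = %g, %d max iterations ...",
                cfg$latent_dim, cfg$reg_u, cfg$max_iter))
fit <- pmf_fit(planted$R, cfg)
message(sprintf("  converged after %d iterations, objective %.4f",
                fit$n_iter, fit$final_objective))

write_factors(fit, file.path(out, "pmf_factors.txt"))
write.csv(data.frame(iteration = seq_along(fit$objective_trace) - 1L,
                     objective = fit$objective_trace),
          file.path(out, "pmf_objective_trace.csv"), row.names = FALSE)

neg <- sample_eval_negatives(planted, n_neg = 200, seed = seed + 2L)
auc <- heldout_auc(fit, planted$hidden, neg)
message(sprintf("  held-out AUC (20 hidden positives vs 200 negatives): %.3f", auc))

# the hidden pairs should also surface in per-target rankings
hits_at_10 <- sum(vapply(unique(planted$hidden$target), function(t) {
  known <- known_drugs(planted$R, t)
  top <- rank_candidates(predict_scores(fit), t, 10, exclude = known)
  sum(planted$hidden$drug[planted$hidden$target == t] %in% top)
}, 0))
message(sprintf("  %d / %d hidden pairs appear in their target's top-10",
                hits_at_10, nrow(planted$hidden)))
write.csv(data.frame(seed = seed, auc = auc, hidden_in_top10 = hits_at_10,
                     n_hidden = nrow(planted$hidden)),
          file.path(out, "pmf_heldout_metrics.csv"), row.names = FALSE)
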