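#!/usr/bin/env Rscript
# Representational geometry of the five sound categories: neural DSM with
# cross-condition mean subtraction, non-metric 2D embedding, and
# multiple-regression RSA against the dissociation and distinction models
# with 1000-iteration repeated hold-out.

library(vocfmri)
dir.create("results", showWarnings = FALSE)
seed <- 20260925L

n_vox <- 60; n_runs <- 12

## a vocalization-dissociating region: the three vocalizations carry
## distinct patterns, the two non-vocalizations share one
truth <- make_category_truth(n_vox, sound_categories(), "dissociation",
                             effect_size = 1, noise_sd = 1,
                             seed = derive_seed(seed, "rsa_means"))
pat <- simulate_beta_patterns(n_vox, n_runs, sound_categories(), truth,
                              seed = derive_seed(seed, "rsa_betas"))

nd <- compute_neural_dsm(pat)
write.table(cbind(label = nd$labels, as.data.frame(round(nd$matrix, 4))),
            "results/neural_dsm.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)

emb <- mds_embed(nd, seed = derive_seed(seed, "mds"))
write.table(data.frame(label = rownames(emb$coords),
                       x = round(emb$coords[, 1], 4),
                       y = round(emb$coords[, 2], 4),
                       stress = round(emb$stress, 5)),
            "results/dsm_embedding.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
cat(sprintf("2D non-metric embedding stress = %.4f\n", emb$stress))

res <- repeated_holdout_rsa(pat, n_iter = 1000,
                            seed = derive_seed(seed, "holdout"))
write.table(transform(res, beta = round(beta, 4), ci_lo = round(ci_lo, 4),
                      ci_hi = round(ci_hi, 4)),
            "results/rsa_model_betas.tsv", sep = "\t", row.names = FALSE,
            quote = FALSE)
print(res)
cat("\nThe dissociation model (vocalizations vs non-vocalizations apart)\n",
    "dominates, as injected; the distinction model picks up the residual\n",
    "within-vocalization spread.\n")
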