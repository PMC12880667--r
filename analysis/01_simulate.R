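#!/usr/bin/env Rscript
# Stage 1: generate the synthetic hemp panel at the study design --
# 46 genotypes x 3 randomized blocks x 5 plants per plot, then thin male
# plants (average two removed per plot). Writes the trial table, the
# per-plot culling counts, and the ground-truth variance components that
# later stages try to recover.

library(rootshoot)

out <- "results/analysis"
dir.create(out, showWarnings = FALSE, recursive = TRUE)
seed <- 20260929 %% 1000

sim <- simulate_hemp_trial(seed = seed)
write_trial_csv(sim$table, file.path(out, "trial.csv"))
write.csv(sim$counts, file.path(out, "culling_counts.csv"),
          row.names = FALSE, quote = FALSE)
write_ground_truth(sim$truth, file.path(out, "ground_truth.csv"))

cat(sprintf("Simulated %d plants in %d plots; %d survived culling (mean %.2f removed/plot).\n",
            46 * 3 * 5, nrow(sim$counts), nrow(sim$table),
            mean(sim$counts$culled_count)))
cat(sprintf("Design heritability spans %.2f-%.2f across the %d traits.\n",
            min(sim$truth$H2), max(sim$truth$H2), nrow(sim$truth)))
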