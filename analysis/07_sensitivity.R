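#!/usr/bin/env Rscript
# Stage 7: culling sensitivity check -- drop every plot that lost four or
# more plants, re-run the variance analysis, and report which traits change
# significance status and how much heritability and genotype rankings move.

library(rootshoot)

out <- "results/analysis"
tbl <- read_trial_csv(file.path(out, "trial_derived.csv"))
counts <- read.csv(file.path(out, "culling_counts.csv"))
herit_full <- read.csv(file.path(out, "heritability.csv"))
traits <- herit_full$trait

filt <- filter_culled_plots(tbl, counts, threshold = 4)
cat(sprintf("Excluded %.0f%% of plots (culled count >= 4).\n",
            100 * filt$excluded_fraction))

herit_filt <- heritability_table(filt$table, traits)
rep <- compare_significance(herit_full, herit_filt, alpha = 0.05,
                            means_full = genotype_means(tbl, traits),
                            means_filtered = genotype_means(filt$table,
                                                            traits))
rep$excluded_plot_fraction <- filt$excluded_fraction

cat("Lost significance:",
    if (length(rep$traits_lost_significance)) paste(rep$traits_lost_significance, collapse = ", ") else "none", "\n")
cat("Gained significance:",
    if (length(rep$traits_gained_significance)) paste(rep$traits_gained_significance, collapse = ", ") else "none", "\n")
cat(sprintf("Median genotype-ranking Spearman rho across traits: %.3f\n",
            median(rep$ranking_correlation, na.rm = TRUE)))
cat(sprintf("Largest |delta H2|: %.3f\n",
            max(abs(rep$heritability_shift$delta_H2), na.rm = TRUE)))

write.csv(data.frame(trait = names(rep$status), status = unname(rep$status),
                     delta_H2 = rep$heritability_shift$delta_H2,
                     spearman_rho = unname(rep$ranking_correlation)),
          file.path(out, "sensitivity.csv"), row.names = FALSE, quote = FALSE)
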