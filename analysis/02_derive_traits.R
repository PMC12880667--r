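#!/usr/bin/env Rscript
# Stage 2: compute the derived traits (specific root length, root mass
# fraction, lateral root length/fraction, total biomass, root:shoot ratio)
# and aggregate plants to genotype means.

library(rootshoot)

out <- "results/analysis"
tbl <- read_trial_csv(file.path(out, "trial.csv"))
tbl <- derive_traits(tbl, length_unit = "mm")
write_trial_csv(tbl, file.path(out, "trial_derived.csv"))

traits <- c("total_root_length", "root_dry_biomass", "shoot_dry_biomass",
            "root_convex_area", "shoot_convex_area", "shoot_height",
            "root_max_depth", "root_crown_max_width", "lower_root_area",
            "avg_root_diameter", "specific_root_length",
            "root_mass_fraction", "lateral_root_length",
            "lateral_root_fraction")
gm <- genotype_means(tbl, traits)
write.csv(gm, file.path(out, "genotype_means.csv"), row.names = FALSE,
          quote = FALSE)

srl <- gm$specific_root_length
cat(sprintf("Genotype-mean SRL spans %.0f-%.0f m/g (panel mean %.0f).\n",
            min(srl), max(srl), mean(srl)))
cat(sprintf("Root mass fraction spans %.3f-%.3f across genotypes.\n",
            min(gm$root_mass_fraction), max(gm$root_mass_fraction)))
big <- gm$genotype[which.max(gm$total_root_length)]
small <- gm$genotype[which.min(gm$total_root_length)]
cat(sprintf("Largest total root length: %s; smallest: %s (%.0f%% difference).\n",
            big, small, 100 * (max(gm$total_root_length) /
                                 min(gm$total_root_length) - 1)))
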