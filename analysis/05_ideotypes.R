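#!/usr/bin/env Rscript
# Stage 5: percentile-rank the genotypes on the six classification traits
# and assign the root-shoot quadrant ideotypes (I big/big, II big root,
# III small/small, IV big shoot), with nearest-group resemblance for
# genotypes that miss a full quadrant.

library(rootshoot)

out <- "results/analysis"
gm <- read.csv(file.path(out, "genotype_means.csv"))

root_traits <- c("root_dry_biomass", "total_root_length", "root_convex_area")
shoot_traits <- c("shoot_dry_biomass", "shoot_convex_area", "shoot_height")
pct <- percentile_ranks(gm, c(root_traits, shoot_traits))
quad <- assign_quadrants(pct, root_traits, shoot_traits, threshold = 50)
write_quadrant_table(quad, pct, file.path(out, "quadrants.csv"))

counts <- table(factor(quad$quadrant,
                       c("I", "II", "III", "IV", "UNASSIGNED")))
cat("Quadrant counts:", paste(names(counts), counts, sep = "=",
                              collapse = ", "), "\n")
un <- quad[quad$quadrant == "UNASSIGNED", ]
cat(sprintf("%d genotypes unassigned; resemblance: %s\n", nrow(un),
            paste(names(table(un$resembles)), table(un$resembles),
                  sep = "=", collapse = ", ")))
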