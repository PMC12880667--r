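#!/usr/bin/env Rscript
# Stage 4: pairwise-complete Pearson correlation structure over genotype
# means and the two headline bivariate regressions (root vs shoot biomass;
# shoot biomass vs root maximum depth).

library(rootshoot)

out <- "results/analysis"
gm <- read.csv(file.path(out, "genotype_means.csv"))
traits <- setdiff(names(gm), "genotype")

corr <- correlation_matrix(gm, traits)
write_correlation_result(corr, out)

reg1 <- bivariate_regression(gm, "shoot_dry_biomass", "root_dry_biomass")
reg2 <- bivariate_regression(gm, "shoot_dry_biomass", "root_max_depth")
write.csv(rbind(reg1, reg2), file.path(out, "regressions.csv"),
          row.names = FALSE, quote = FALSE)

cat(sprintf("Root vs shoot biomass over %d genotypes: r = %.2f (p = %.2g).\n",
            reg1$n, reg1$r, reg1$p))
cat(sprintf("Shoot biomass vs root max depth: r = %.2f (p = %.2g).\n",
            reg2$r, reg2$p))
neg <- sum(corr$R["specific_root_length", ] < 0, na.rm = TRUE)
cat(sprintf("Specific root length correlates negatively with %d of %d other traits.\n",
            neg, length(traits) - 1))
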