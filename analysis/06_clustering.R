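#!/usr/bin/env Rscript
# Stage 6: PCA of the scaled classification traits, K-means at k = 3 and 4
# on the full set of component scores, bootstrap Jaccard stability per
# cluster, and concordance of the clusters with the quadrant grouping.

library(rootshoot)

out <- "results/analysis"
gm <- read.csv(file.path(out, "genotype_means.csv"))
quad <- read.csv(file.path(out, "quadrants.csv"))
seed <- 20260929 %% 1000

traits <- c("root_dry_biomass", "total_root_length", "root_convex_area",
            "shoot_dry_biomass", "shoot_convex_area", "shoot_height")
pca <- standardize_and_pca(gm, traits)
cat(sprintf("PC1 and PC2 explain %.0f%% and %.0f%% of trait variance.\n",
            100 * pca$variance_explained[1], 100 * pca$variance_explained[2]))

qlab <- setNames(quad$quadrant, quad$genotype)
rows <- list()
for (k in c(3, 4)) {
  stab <- bootstrap_jaccard(pca$scores, k = k, B = 100, n_starts = 25,
                            seed = seed + k)
  conc <- concordance(stab$labels, qlab)
  cat(sprintf("k=%d: per-cluster Jaccard stability %s; ARI vs quadrants %.2f\n",
              k, paste(sprintf("%.2f", stab$jaccard), collapse = "/"),
              conc$ari))
  rows[[as.character(k)]] <- data.frame(
    k = k, cluster = seq_len(k), jaccard = stab$jaccard,
    dissolved = stab$dissolved)
  write.csv(data.frame(genotype = names(stab$labels), cluster = stab$labels),
            file.path(out, sprintf("clusters_k%d.csv", k)),
            row.names = FALSE, quote = FALSE)
}
write.csv(do.call(rbind, rows), file.path(out, "cluster_stability.csv"),
          row.names = FALSE, quote = FALSE)
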