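make_counts <- function(tbl, counts_map) {
  plots <- unique(tbl[c("genotype", "block")])
  plots$culled_count <- counts_map(nrow(plots))
  plots
}

test_that("plot filtering removes exactly the heavily culled plots", {
  sim <- simulate_hemp_trial(seed = 41, culling_rate = 0)
  counts <- sim$counts
  expect_true(all(counts$culled_count == 0))
  none <- filter_culled_plots(sim$table, counts, threshold = 4)
  expect_identical(none$table, sim$table)
  expect_equal(none$excluded_fraction, 0)

  counts$culled_count[c(1, 50)] <- 4
  filt <- filter_culled_plots(sim$table, counts, threshold = 4)
  expect_equal(filt$excluded_fraction, 2 / nrow(counts))
  gone <- paste(counts$genotype[c(1, 50)], counts$block[c(1, 50)])
  kept <- paste(filt$table$genotype, filt$table$block)
  expect_false(any(kept %in% gone))
  expect_error(filter_culled_plots(sim$table, counts, threshold = 0),
               "threshold")
})

test_that("simple count layouts give the expected fraction", {
  tbl <- data.frame(genotype = rep("g", 3), block = c("B1", "B2", "B3"),
                    plant = "P1", y = 1:3)
  counts <- data.frame(genotype = "g", block = c("B1", "B2", "B3"),
                       culled_count = c(0, 0, 4))
  filt <- filter_culled_plots(tbl, counts)
  expect_equal(filt$excluded_fraction, 1 / 3)
  expect_equal(nrow(filt$table), 2)
})

test_that("the excluded fraction matches the culling model's tail probability", {
  # capped Poisson with n = 5: the count reaches 4 exactly when X >= 4
  sim <- simulate_hemp_trial(seed = 47,
                             config = local({
                               cfg <- default_trial_config(seed = 47)
                               cfg$n_genotypes <- 300L
                               cfg
                             }))
  filt <- filter_culled_plots(sim$table, sim$counts, threshold = 4)
  tail_prob <- ppois(3, 2, lower.tail = FALSE)
  expect_equal(filt$excluded_fraction, tail_prob, tolerance = 0.15)
})

test_that("filtering then analyzing equals analyzing the pre-subset table", {
  sim <- simulate_hemp_trial(seed = 43)
  tbl <- derive_traits(sim$table)
  traits <- c("root_dry_biomass", "shoot_dry_biomass", "specific_root_length")
  filt <- filter_culled_plots(tbl, sim$counts, threshold = 4)
  manual <- tbl[!paste(tbl$genotype, tbl$block) %in%
                  paste(filt$excluded_plots$genotype,
                        filt$excluded_plots$block), ]
  expect_gt(filt$excluded_fraction, 0)
  expect_equal(heritability_table(filt$table, traits),
               heritability_table(manual, traits))
  expect_equal(genotype_means(filt$table, traits),
               genotype_means(manual, traits), ignore_attr = TRUE)
})

test_that("a threshold above the maximum count leaves the analysis unchanged", {
  sim <- simulate_hemp_trial(seed = 53)
  traits <- c("root_dry_biomass", "shoot_height")
  filt <- filter_culled_plots(sim$table, sim$counts,
                              threshold = max(sim$counts$culled_count) + 1)
  expect_equal(filt$excluded_fraction, 0)
  expect_equal(heritability_table(filt$table, traits),
               heritability_table(sim$table, traits))
})

test_that("significance comparison classifies traits and rejects mismatched lists", {
  full <- data.frame(trait = c("a", "b", "c", "d"),
                     p = c(0.01, 0.20, 0.03, 0.40),
                     H2 = c(0.6, 0.3, 0.5, 0.2))
  filt <- data.frame(trait = c("a", "b", "c", "d"),
                     p = c(0.02, 0.04, 0.30, 0.60),
                     H2 = c(0.55, 0.35, 0.45, 0.15))
  rep <- compare_significance(full, filt)
  expect_equal(rep$traits_lost_significance, "c")
  expect_equal(rep$traits_gained_significance, "b")
  expect_equal(unname(rep$status),
               c("stable-significant", "gained", "lost",
                 "stable-nonsignificant"))
  expect_equal(rep$heritability_shift$delta_H2, c(-0.05, 0.05, -0.05, -0.05))
  expect_length(intersect(rep$traits_lost_significance,
                          rep$traits_gained_significance), 0)

  same <- compare_significance(full, full)
  expect_length(same$traits_lost_significance, 0)
  expect_length(same$traits_gained_significance, 0)

  expect_error(compare_significance(full, filt[1:3, ]), "differ")
})

test_that("genotype ranking correlations are reported when means are supplied", {
  sim <- simulate_hemp_trial(seed = 59)
  traits <- c("root_dry_biomass", "shoot_dry_biomass")
  filt <- filter_culled_plots(sim$table, sim$counts, threshold = 4)
  h_full <- heritability_table(sim$table, traits)
  h_filt <- heritability_table(filt$table, traits)
  rep <- compare_significance(h_full, h_filt,
                              means_full = genotype_means(sim$table, traits),
                              means_filtered = genotype_means(filt$table,
                                                              traits))
  expect_equal(names(rep$ranking_correlation), traits)
  # excluding ~12-15% of plots should barely move genotype rankings
  expect_true(all(rep$ranking_correlation > 0.8))
})
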