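raw_row <- function(total = 1000, d2 = 300, d3 = 200, root = 2, shoot = 18) {
  data.frame(genotype = "G01", block = "B1", plant = "P1", culled = FALSE,
             total_root_length = total, root_length_diam2 = d2,
             root_length_diam3 = d3, root_dry_biomass = root,
             shoot_dry_biomass = shoot, stringsAsFactors = FALSE)
}

test_that("derived traits match their defining ratios", {
  # 100 m of root at 2 g -> SRL 50 m/g (lengths given in metres here)
  d <- derive_traits(raw_row(total = 100, d2 = 30, d3 = 20, root = 2),
                     length_unit = "m")
  expect_equal(d$specific_root_length, 50)

  # 1 g root, 9 g shoot -> RMF 0.1
  d <- derive_traits(raw_row(root = 1, shoot = 9))
  expect_equal(d$root_mass_fraction, 0.1)
  expect_equal(d$total_biomass, 10)
  expect_equal(d$root_shoot_ratio, 1 / 9)

  # classes 300 + 200 of 1000 mm -> LRL 500 mm, LRF 0.5; SRL converts mm -> m
  d <- derive_traits(raw_row(total = 1000, d2 = 300, d3 = 200, root = 2))
  expect_equal(d$lateral_root_length, 500)
  expect_equal(d$lateral_root_fraction, 0.5)
  expect_equal(d$specific_root_length, 1 / 2)
})

test_that("missing or zero denominators give missing values, never errors", {
  d <- derive_traits(rbind(raw_row(root = 0), raw_row(total = 0),
                           raw_row(root = NA), raw_row(shoot = NA)))
  expect_true(is.na(d$specific_root_length[1]))
  expect_true(is.na(d$lateral_root_fraction[2]))
  expect_true(is.na(d$root_mass_fraction[3]))
  expect_true(is.na(d$root_shoot_ratio[4]))
  expect_true(is.na(d$root_mass_fraction[4]))
})

test_that("absent raw columns are rejected with the missing names listed", {
  bad <- raw_row()
  bad$root_dry_biomass <- NULL
  bad$root_length_diam3 <- NULL
  expect_error(derive_traits(bad), "root_dry_biomass")
  expect_error(derive_traits(bad), "root_length_diam3")
})

test_that("column mapping supports foreign export headers", {
  d <- raw_row()
  names(d)[names(d) == "total_root_length"] <- "Total.Root.Length.mm"
  out <- derive_traits(d, col_map = c(total_root_length = "Total.Root.Length.mm"))
  expect_equal(out$specific_root_length, 0.5)
})

test_that("derivation is idempotent and scale-consistent", {
  sim <- simulate_hemp_trial(seed = 6)
  once <- derive_traits(sim$table)
  twice <- derive_traits(once)
  expect_identical(once, twice)

  doubled <- sim$table
  for (cl in c("total_root_length", "root_length_diam1",
               "root_length_diam2", "root_length_diam3"))
    doubled[[cl]] <- 2 * doubled[[cl]]
  d1 <- derive_traits(sim$table); d2 <- derive_traits(doubled)
  expect_equal(d2$lateral_root_length, 2 * d1$lateral_root_length)
  expect_equal(d2$lateral_root_fraction, d1$lateral_root_fraction)
  # structural invariants on simulated data
  expect_true(all(d1$lateral_root_fraction <= 1 + 1e-12, na.rm = TRUE))
  expect_true(all(d1$root_mass_fraction >= 0 & d1$root_mass_fraction <= 1,
                  na.rm = TRUE))
})

test_that("genotype means pool plants with per-cell sample sizes", {
  tbl <- data.frame(genotype = rep("G01", 3), block = c("B1", "B1", "B2"),
                    plant = c("P1", "P2", "P1"), culled = FALSE,
                    y = c(1, 2, 3), z = NA_real_, stringsAsFactors = FALSE)
  expect_message(gm <- genotype_means(tbl, c("y", "z")), "no observations")
  expect_equal(gm$y, 2)
  expect_true(is.na(gm$z))
  n <- attr(gm, "n")
  expect_equal(unname(n[, "y"]), 3)
  expect_equal(unname(n[, "z"]), 0)
})

test_that("block-mean aggregation differs from pooling exactly when plots are unbalanced", {
  tbl <- data.frame(genotype = "G01", block = c("B1", "B1", "B1", "B2"),
                    plant = paste0("P", 1:4), culled = FALSE,
                    y = c(1, 2, 3, 10), stringsAsFactors = FALSE)
  pooled <- genotype_means(tbl, "y")
  by_block <- genotype_means(tbl, "y", by_block = TRUE)
  expect_equal(pooled$y, 4)
  expect_equal(by_block$y, (2 + 10) / 2)
})

test_that("a simulated genotype mean converges to mu + g_i", {
  cfg <- trial_config(2, 2, 5000, "y", 100, sigma2_g = 4, sigma2_b = 0,
                      sigma2_e = 9, nonneg = FALSE, seed = 12)
  tbl <- simulate_trial(cfg)
  g <- attr(tbl, "truth")$genotype_effects
  gm <- genotype_means(tbl, "y")
  # mean of 10^4 residuals: SE = 3/100, so a 4 SE window is 0.12
  expect_equal(gm$y, 100 + unname(g[gm$genotype, "y"]), tolerance = 1.3e-3)
})
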