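test_that("heritability follows its defining formula and edge cases", {
  h <- broad_sense_heritability(list(sigma2_g = 1, sigma2_b = 0,
                                     sigma2_e = 0, r = 3))
  expect_equal(h$H2, 1)
  h <- broad_sense_heritability(list(sigma2_g = 2, sigma2_b = 0.5,
                                     sigma2_e = 3, r = 3))
  expect_equal(h$H2, 2 / 3)
  h <- broad_sense_heritability(list(sigma2_g = 0, sigma2_b = 0,
                                     sigma2_e = 0, r = 3))
  expect_true(is.na(h$H2))
})

test_that("H2 is increasing in sigma2_g and decreasing in sigma2_e", {
  h2 <- function(sg, se) broad_sense_heritability(
    list(sigma2_g = sg, sigma2_b = 0, sigma2_e = se, r = 3))$H2
  sg_grid <- seq(0.1, 5, length.out = 20)
  expect_true(all(diff(vapply(sg_grid, h2, numeric(1), se = 2)) > 0))
  se_grid <- seq(0.1, 5, length.out = 20)
  expect_true(all(diff(vapply(se_grid, function(se) h2(1, se),
                              numeric(1))) < 0))
})

test_that("the genotype F-test is exactly zero when genotypes are identical", {
  tbl <- data.frame(genotype = rep(c("A", "B"), each = 6),
                    block = rep(rep(c("B1", "B2", "B3"), each = 2), 2),
                    plant = rep(c("P1", "P2"), 6), culled = FALSE,
                    y = rep(c(1.2, 3.4, 0.8, 2.2, 1.7, 2.9), 2))
  res <- fit_genotype_anova(tbl, "y")
  expect_equal(res$F_statistic, 0, tolerance = 1e-10)
  expect_equal(res$df_numerator, 1)
  expect_equal(res$df_denominator, nrow(tbl) - 2 - 3 + 1)
})

test_that("a constant trait gives a degenerate fit with missing F and p", {
  tbl <- data.frame(genotype = rep(c("A", "B"), each = 4),
                    block = rep(c("B1", "B2"), 4), plant = "P1",
                    y = 5)
  res <- fit_genotype_anova(tbl, "y")
  expect_true(is.na(res$F_statistic))
  expect_true(is.na(res$p_value))
})

test_that("a strong genotype effect is detected at the trial design size", {
  for (s in 1:5) {
    cfg <- config_for_h2(0.8, seed = 40 + s)
    tbl <- simulate_trial(cfg)
    expect_lt(fit_genotype_anova(tbl, "y")$p_value, 0.05)
  }
})

test_that("EMS truncates negative solutions to zero and flags them", {
  # all genotype structure removed: MS_genotype < MS_residual is common
  set.seed(7)
  found <- FALSE
  for (s in 1:20) {
    cfg <- one_trait_config(sigma2_g = 0, sigma2_b = 0, n_genotypes = 8,
                            seed = 100 + s)
    tbl <- simulate_trial(cfg)
    vc <- estimate_variance_components(tbl, "y", method = "ems")
    expect_gte(vc$sigma2_g, 0)
    expect_gte(vc$sigma2_b, 0)
    if (vc$truncated && vc$sigma2_g == 0) found <- TRUE
  }
  expect_true(found)
})

test_that("REML null-case estimates concentrate at zero", {
  ests <- vapply(1:30, function(s) {
    tbl <- simulate_trial(one_trait_config(sigma2_g = 0, seed = 200 + s))
    estimate_variance_components(tbl, "y")$sigma2_g
  }, numeric(1))
  expect_equal(median(ests), 0, tolerance = 1e-8)
})

test_that("plant-scale and plot-mean-scale estimates tell one consistent story", {
  cfg <- one_trait_config(seed = 77)
  tbl <- simulate_trial(cfg)
  a <- estimate_variance_components(tbl, "y", scale = "plot_mean")
  b <- estimate_variance_components(tbl, "y", scale = "plant")
  # the scales pool different residual strata (plot means keep the
  # genotype-by-block stratum separate; the plant fit pools it with the
  # within-plot stratum), so components agree closely but not exactly
  expect_equal(a$sigma2_g, b$sigma2_g, tolerance = 0.05)
  expect_equal(a$sigma2_e, b$sigma2_e / 5, tolerance = 0.15)
  # plant-scale REML pools the plot and within-plot strata by likelihood
  # weight rather than by df, so it tracks the EMS solution only closely;
  # the exact equivalence lives on the (saturated) plot-mean scale
  d <- estimate_variance_components(tbl, "y", method = "ems",
                                    scale = "plant")
  expect_equal(b$sigma2_g, d$sigma2_g, tolerance = 1e-3)
  expect_equal(b$sigma2_e, d$sigma2_e, tolerance = 1e-3)
})

test_that("unbalanced plots trigger the harmonic-mean EMS warning", {
  sim <- simulate_hemp_trial(seed = 21)
  expect_warning(
    estimate_variance_components(sim$table, "root_dry_biomass",
                                 method = "ems", scale = "plant"),
    "harmonic mean")
})

test_that("the per-trait results table is complete and flags significance coherently", {
  sim <- simulate_hemp_trial(seed = 31)
  tbl <- derive_traits(sim$table)
  out <- heritability_table(tbl, c("root_dry_biomass", "shoot_dry_biomass",
                                   "specific_root_length"))
  expect_equal(out$trait, c("root_dry_biomass", "shoot_dry_biomass",
                            "specific_root_length"))
  expect_true(all(out$H2 >= 0 & out$H2 <= 1))
  expect_true(all(out$p >= 0 & out$p <= 1))
  expect_true(all(out$r == 3))
  out_bh <- heritability_table(tbl, c("root_dry_biomass", "shoot_dry_biomass"),
                               adjust_p = "BH")
  expect_true(all(out_bh$p_adj >= out_bh$p))
})
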