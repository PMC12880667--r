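#' Genotype effect F-test in the genotype x block design
#'
#' Fits the linear mixed model `trait ~ genotype + (1 | block)` (genotype
#' fixed, block random, REML) and tests the genotype effect with an F
#' statistic. Denominator degrees of freedom use the between-within
#' approximation `df_den = N - G - B + 1`, exact for balanced designs.
#'
#' @param table trial table.
#' @param trait trait column name.
#' @return data.frame: trait, F_statistic, df_numerator, df_denominator,
#'   p_value, n. A trait constant across all plants gives a degenerate fit
#'   with missing F and p.
#' @export
fit_genotype_anova <- function(table, trait) {
  check_columns(table, c("genotype", "block", trait), "trial table")
  d <- data.frame(y = table[[trait]],
                  genotype = factor(table$genotype),
                  block = factor(table$block))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  G <- nlevels(droplevels(d$genotype))
  B <- nlevels(droplevels(d$block))
  if (G < 2 || B < 2) stop("need >= 2 genotypes and >= 2 blocks")
  out <- data.frame(trait = trait, F_statistic = NA_real_,
                    df_numerator = G - 1L,
                    df_denominator = nrow(d) - G - B + 1L,
                    p_value = NA_real_, n = nrow(d),
                    stringsAsFactors = FALSE)
  if (stats::var(d$y) == 0) return(out)  # degenerate: constant trait
  fit <- tryCatch(
    suppressMessages(lme4::lmer(
      y ~ genotype + (1 | block), data = d, REML = TRUE,
      control = lme4::lmerControl(check.conv.singular = "ignore",
                                  calc.derivs = FALSE))),
    error = function(e) NULL)
  if (is.null(fit)) return(out)
  aov_tab <- stats::anova(fit)
  out$F_statistic <- aov_tab[["F value"]][1]
  out$p_value <- stats::pf(out$F_statistic, out$df_numerator,
                           out$df_denominator, lower.tail = FALSE)
  out
}

#' Estimate genotype, block and residual variance components
#'
#' Default scale is `"plot_mean"`: plants are first averaged to
#' genotype-by-block plot means, so the residual is the plot-mean residual
#' and the heritability denominator divides it by `r` once. `"plant"` keeps
#' individual plants (residual is plant-level).
#'
#' `method = "reml"` fits `y ~ (1|genotype) + (1|block)` with lme4.
#' `method = "ems"` uses the balanced two-way expected-mean-squares
#' solution: on the plot-mean scale `sg = (MS_G - MS_E) / r`,
#' `sb = (MS_B - MS_E) / G`; on the plant scale the divisors gain the
#' (harmonic mean, with a warning if unequal) plot size. Negative EMS
#' solutions are truncated to zero and flagged.
#'
#' @param table trial table.
#' @param trait trait column name.
#' @param method `"reml"` (default) or `"ems"`.
#' @param scale `"plot_mean"` (default) or `"plant"`.
#' @return list of class `variance_components`: sigma2_g, sigma2_b,
#'   sigma2_e, r, method, scale, truncated (logical), n_obs.
#' @export
estimate_variance_components <- function(table, trait,
                                         method = c("reml", "ems"),
                                         scale = c("plot_mean", "plant")) {
  method <- match.arg(method)
  scale <- match.arg(scale)
  check_columns(table, c("genotype", "block", trait), "trial table")
  d <- data.frame(y = table[[trait]],
                  genotype = factor(table$genotype),
                  block = factor(table$block))
  d <- d[stats::complete.cases(d), , drop = FALSE]
  d$genotype <- droplevels(d$genotype); d$block <- droplevels(d$block)
  G <- nlevels(d$genotype); B <- nlevels(d$block)
  if (G < 2 || B < 2) stop("need >= 2 genotypes and >= 2 blocks")

  if (scale == "plot_mean") {
    cell <- tapply(d$y, list(d$genotype, d$block), mean)
    dd <- data.frame(
      y = as.vector(cell),
      genotype = factor(rep(rownames(cell), times = B)),
      block = factor(rep(colnames(cell), each = G)))
    dd <- dd[!is.na(dd$y), , drop = FALSE]
    n_per_cell <- 1
  } else {
    dd <- d
    n_per_cell <- as.vector(table(d$genotype, d$block))
    n_per_cell <- n_per_cell[n_per_cell > 0]
  }

  if (method == "reml") {
    # rhoend far below default so REML matches the closed-form EMS solution
    # on balanced data to ~1e-8; at that precision bobyqa sometimes reports
    # a failed final trust-region step, which is not a real non-convergence
    fit <- withCallingHandlers(
      suppressMessages(lme4::lmer(
        y ~ (1 | genotype) + (1 | block), data = dd, REML = TRUE,
        control = lme4::lmerControl(
          check.conv.singular = "ignore", optimizer = "bobyqa",
          optCtrl = list(rhobeg = 0.2, rhoend = 2e-13)))),
      warning = function(w) {
        if (grepl("bobyqa", conditionMessage(w)))
          invokeRestart("muffleWarning")
      })
    vc <- as.data.frame(lme4::VarCorr(fit))
    get <- function(grp) vc$vcov[vc$grp == grp]
    sg <- get("genotype"); sb <- get("block"); se <- get("Residual")
    truncated <- any(c(sg, sb) < 1e-12)
  } else {
    cell_counts <- as.vector(table(dd$genotype, dd$block))
    balanced <- length(unique(cell_counts)) == 1 && all(cell_counts > 0)
    nbar <- if (scale == "plant") {
      if (length(unique(n_per_cell)) > 1) {
        warning("unbalanced plot sizes with method='ems': using harmonic mean")
        length(n_per_cell) / sum(1 / n_per_cell)
      } else n_per_cell[1]
    } else 1
    if (!balanced && scale == "plot_mean")
      warning("incomplete genotype x block cells with method='ems'")
    ms <- stats::anova(stats::lm(y ~ genotype + block, data = dd))
    ms_g <- ms["genotype", "Mean Sq"]
    ms_b <- ms["block", "Mean Sq"]
    ms_e <- ms["Residuals", "Mean Sq"]
    sg_raw <- (ms_g - ms_e) / (B * nbar)
    sb_raw <- (ms_b - ms_e) / (G * nbar)
    truncated <- sg_raw < 0 || sb_raw < 0
    sg <- max(sg_raw, 0); sb <- max(sb_raw, 0); se <- ms_e
  }
  structure(list(trait = trait, sigma2_g = sg, sigma2_b = sb, sigma2_e = se,
                 r = B, method = toupper(method), scale = scale,
                 truncated = truncated, n_obs = nrow(dd)),
            class = "variance_components")
}

#' Broad-sense heritability from variance components
#'
#' `H2 = sigma2_g / (sigma2_g + sigma2_e / r)`, the repeatability of a
#' genotype mean over `r` replicate blocks; on the default plot-mean scale
#' `sigma2_e` is the plot-mean residual variance.
#'
#' @param components a `variance_components` object (or list with fields
#'   sigma2_g, sigma2_e, r).
#' @return list of class `heritability_result`: trait, H2, components.
#'   `H2` is missing when both variances are zero.
#' @export
broad_sense_heritability <- function(components) {
  sg <- components$sigma2_g; se <- components$sigma2_e; r <- components$r
  stopifnot(sg >= 0, se >= 0, r >= 1)
  denom <- sg + se / r
  h2 <- if (denom == 0) NA_real_ else sg / denom
  structure(list(trait = components$trait %||% NA_character_,
                 H2 = h2, components = components),
            class = "heritability_result")
}

#' Per-trait genotype test, variance components and heritability table
#'
#' Runs [fit_genotype_anova()] (plant scale, genotype fixed) and
#' [estimate_variance_components()] + [broad_sense_heritability()]
#' (random genotype) for each trait and assembles the module's standard
#' results table.
#'
#' @param table trial table.
#' @param traits character vector of trait columns.
#' @param method component estimation method, `"reml"` or `"ems"`.
#' @param scale component estimation scale, see
#'   [estimate_variance_components()].
#' @param adjust_p optional p-value adjustment across traits
#'   (`"none"`, default matching per-trait reporting, or `"BH"`).
#' @return data.frame: trait, F, df1, df2, p, sigma2_g, sigma2_b, sigma2_e,
#'   r, H2, method, truncated.
#' @export
heritability_table <- function(table, traits, method = "reml",
                               scale = "plot_mean", adjust_p = "none") {
  rows <- lapply(traits, function(tr) {
    a <- fit_genotype_anova(table, tr)
    vc <- estimate_variance_components(table, tr, method = method,
                                       scale = scale)
    h <- broad_sense_heritability(vc)
    data.frame(trait = tr, F = a$F_statistic, df1 = a$df_numerator,
               df2 = a$df_denominator, p = a$p_value,
               sigma2_g = vc$sigma2_g, sigma2_b = vc$sigma2_b,
               sigma2_e = vc$sigma2_e, r = vc$r, H2 = h$H2,
               method = vc$method, truncated = vc$truncated,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (!identical(adjust_p, "none")) out$p_adj <- stats::p.adjust(out$p, adjust_p)
  rownames(out) <- NULL
  out
}
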