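#' Build and validate a synthetic trial configuration
#'
#' Defines a randomized-block multi-trait phenotyping trial with additive
#' genotype + block + residual variance components per trait. Genotype effect
#' vectors are multivariate normal with covariance
#' `diag(sqrt(sigma2_g)) %*% genetic_correlation %*% diag(sqrt(sigma2_g))`;
#' residuals are multivariate normal across traits with an analogous
#' `residual_correlation` (whole-plant vigor: a plant with an unusually large
#' shoot tends to have an unusually large root, beyond what its genotype
#' predicts); block effects are univariate and independent across traits.
#'
#' @param n_genotypes number of genotypes.
#' @param n_blocks number of replicate blocks (the `r` of the heritability
#'   denominator); must be at least 2.
#' @param n_plants_per_plot plants sown per genotype-by-block plot.
#' @param trait_names character vector of trait identifiers.
#' @param trait_means per-trait location (units per trait: lengths mm,
#'   masses g, areas mm^2, ratios unitless).
#' @param sigma2_g,sigma2_b,sigma2_e per-trait genotype, block and
#'   plant-level residual variances; all must be nonnegative.
#' @param genetic_correlation symmetric positive-semidefinite matrix with
#'   unit diagonal over traits.
#' @param residual_correlation as `genetic_correlation`, for the within-plant
#'   residuals; defaults to the identity (independent residuals).
#' @param culling_rate expected number of male plants removed per plot.
#' @param missing_rate probability that an individual trait measurement is
#'   missing at random (exercises pairwise-complete handling); default 0.
#' @param nonneg logical: clamp simulated trait values at zero (lengths,
#'   masses and areas cannot be negative). Default TRUE.
#' @param seed integer seed; expanded into independent per-stage substreams.
#' @return a validated `trial_config` list.
#' @export
trial_config <- function(n_genotypes, n_blocks, n_plants_per_plot,
                         trait_names, trait_means,
                         sigma2_g, sigma2_b, sigma2_e,
                         genetic_correlation = NULL,
                         residual_correlation = NULL,
                         culling_rate = 0, missing_rate = 0,
                         nonneg = TRUE, seed = 1L) {
  p <- length(trait_names)
  if (is.null(genetic_correlation)) genetic_correlation <- diag(p)
  if (is.null(residual_correlation)) residual_correlation <- diag(p)
  cfg <- list(
    n_genotypes = as.integer(n_genotypes),
    n_blocks = as.integer(n_blocks),
    n_plants_per_plot = as.integer(n_plants_per_plot),
    trait_names = as.character(trait_names),
    trait_means = stats::setNames(as.numeric(trait_means), trait_names),
    sigma2_g = stats::setNames(as.numeric(sigma2_g), trait_names),
    sigma2_b = stats::setNames(as.numeric(sigma2_b), trait_names),
    sigma2_e = stats::setNames(as.numeric(sigma2_e), trait_names),
    genetic_correlation = as.matrix(genetic_correlation),
    residual_correlation = as.matrix(residual_correlation),
    culling_rate = as.numeric(culling_rate),
    missing_rate = as.numeric(missing_rate),
    nonneg = isTRUE(nonneg),
    seed = as.integer(seed)
  )
  class(cfg) <- "trial_config"
  validate_trial_config(cfg)
  cfg
}

validate_trial_config <- function(cfg) {
  p <- length(cfg$trait_names)
  if (cfg$n_blocks < 2) stop("n_blocks must be >= 2 (heritability uses r replicate blocks)")
  if (cfg$n_genotypes < 1 || cfg$n_plants_per_plot < 1)
    stop("n_genotypes and n_plants_per_plot must be >= 1")
  for (nm in c("trait_means", "sigma2_g", "sigma2_b", "sigma2_e")) {
    if (length(cfg[[nm]]) != p) stop(nm, " must have one entry per trait")
  }
  for (nm in c("sigma2_g", "sigma2_b", "sigma2_e")) {
    if (any(cfg[[nm]] < 0)) stop(nm, " must be nonnegative")
  }
  if (cfg$culling_rate < 0) stop("culling_rate must be >= 0")
  if (cfg$missing_rate < 0 || cfg$missing_rate > 1)
    stop("missing_rate must be in [0, 1]")
  check_correlation <- function(R, what) {
    if (!all(dim(R) == c(p, p)))
      stop(what, " must be a ", p, "x", p, " matrix")
    if (max(abs(R - t(R))) > 1e-10) stop(what, " must be symmetric")
    if (max(abs(diag(R) - 1)) > 1e-10) stop(what, " must have unit diagonal")
    ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8)
      stop(what, " is not positive semidefinite (min eigenvalue ",
           format(min(ev)), ")")
  }
  check_correlation(cfg$genetic_correlation, "genetic_correlation")
  check_correlation(cfg$residual_correlation, "residual_correlation")
  invisible(cfg)
}

# Matrix square root for a PSD covariance; eigen-based so exactly singular
# correlation structures (e.g. two perfectly correlated traits) are allowed.
psd_sqrt <- function(S) {
  e <- eigen(S, symmetric = TRUE)
  e$vectors %*% (sqrt(pmax(e$values, 0)) * t(e$vectors))
}

# Correlated draws: n x p matrix with rows ~ MVN(0, D R D), D = diag(sd).
rmvn_rows <- function(n, sd, R) {
  p <- length(sd)
  S <- (sd %o% sd) * R
  matrix(stats::rnorm(n * p), n, p) %*% psd_sqrt(S)
}

#' Simulate a randomized-block phenotyping trial
#'
#' Draws `y[trait, ijk] = mu_trait + g_i[trait] + b_j[trait] + e_ijk[trait]`
#' for every genotype i, block j and plant k. All plants are present and
#' `culled` is FALSE throughout; see [apply_culling()] for male removal.
#'
#' @param config a [trial_config()].
#' @return data.frame with columns `genotype`, `block`, `plant`, `culled` and
#'   one column per trait; `n_genotypes * n_blocks * n_plants_per_plot` rows.
#'   The attached `"truth"` attribute carries the realized genotype effects
#'   and the configured components (see [ground_truth()]).
#' @export
simulate_trial <- function(config) {
  validate_trial_config(config)
  cfg <- config
  G <- cfg$n_genotypes; B <- cfg$n_blocks; n <- cfg$n_plants_per_plot
  p <- length(cfg$trait_names)
  N <- G * B * n

  set.seed(sub_seed(cfg$seed, "effects"))
  g_eff <- rmvn_rows(G, sqrt(cfg$sigma2_g), cfg$genetic_correlation)
  b_eff <- matrix(stats::rnorm(B * p, sd = rep(sqrt(cfg$sigma2_b), each = B)),
                  B, p)
  e_eff <- rmvn_rows(N, sqrt(cfg$sigma2_e), cfg$residual_correlation)

  geno_id <- sprintf("G%02d", seq_len(G))
  block_id <- sprintf("B%d", seq_len(B))
  plant_id <- sprintf("P%d", seq_len(n))
  idx_g <- rep(seq_len(G), each = B * n)
  idx_b <- rep(rep(seq_len(B), each = n), times = G)
  idx_p <- rep(seq_len(n), times = G * B)

  y <- matrix(rep(cfg$trait_means, each = N), N, p) +
    g_eff[idx_g, , drop = FALSE] + b_eff[idx_b, , drop = FALSE] + e_eff
  if (cfg$nonneg) y <- pmax(y, 0)
  colnames(y) <- cfg$trait_names

  if (cfg$missing_rate > 0) {
    set.seed(sub_seed(cfg$seed, "missing"))
    drop <- matrix(stats::runif(N * p) < cfg$missing_rate, N, p)
    y[drop] <- NA_real_
  }

  tbl <- data.frame(
    genotype = geno_id[idx_g],
    block = block_id[idx_b],
    plant = plant_id[idx_p],
    culled = FALSE,
    y,
    stringsAsFactors = FALSE, check.names = FALSE
  )
  rownames(g_eff) <- geno_id
  colnames(g_eff) <- cfg$trait_names
  attr(tbl, "truth") <- list(config = cfg, genotype_effects = g_eff,
                             block_effects = b_eff,
                             components = ground_truth(cfg))
  tbl
}

#' Ground-truth variance components and heritability for a configuration
#'
#' The plot-mean residual variance is `sigma2_e / n_plants_per_plot` and the
#' design heritability is `H2 = sigma2_g / (sigma2_g + sigma2_e_plot / r)`,
#' i.e. the repeatability of a genotype mean over `r` replicate blocks of
#' full plots.
#'
#' @param config a [trial_config()].
#' @return data.frame: trait, sigma2_g, sigma2_b, sigma2_e (plant scale),
#'   sigma2_e_plot, r, H2.
#' @export
ground_truth <- function(config) {
  cfg <- config
  e_plot <- cfg$sigma2_e / cfg$n_plants_per_plot
  denom <- cfg$sigma2_g + e_plot / cfg$n_blocks
  data.frame(
    trait = cfg$trait_names,
    sigma2_g = unname(cfg$sigma2_g),
    sigma2_b = unname(cfg$sigma2_b),
    sigma2_e = unname(cfg$sigma2_e),
    sigma2_e_plot = unname(e_plot),
    r = cfg$n_blocks,
    H2 = unname(ifelse(denom > 0, cfg$sigma2_g / denom, NA_real_)),
    stringsAsFactors = FALSE
  )
}

#' Remove male plants from a simulated trial
#'
#' Per genotype-by-block plot, the number of plants removed is drawn as a
#' Poisson variate with mean `culling_rate`, capped at `n_plants - 1` so at
#' least one plant survives; the removed plants are a uniform random subset
#' of the plot. Mirrors thinning of male plants after sex expression.
#'
#' @param table trial table from [simulate_trial()].
#' @param culling_rate expected removals per plot (the study averaged two).
#' @param seed integer seed.
#' @return list with `table` (surviving rows, `culled` still FALSE) and
#'   `counts` (data.frame genotype, block, culled_count) for the
#'   sensitivity analysis.
#' @export
apply_culling <- function(table, culling_rate, seed = 1L) {
  if (culling_rate < 0) stop("culling_rate must be >= 0")
  check_columns(table, c("genotype", "block", "plant"), "trial table")
  plot_key <- interaction(table$genotype, table$block, drop = TRUE, sep = "\r")
  plots <- unique(data.frame(genotype = table$genotype, block = table$block,
                             key = as.character(plot_key),
                             stringsAsFactors = FALSE))
  set.seed(sub_seed(seed, "culling"))
  keep <- rep(TRUE, nrow(table))
  counts <- integer(nrow(plots))
  for (i in seq_len(nrow(plots))) {
    rows <- which(as.character(plot_key) == plots$key[i])
    n_here <- length(rows)
    k <- if (culling_rate == 0) 0L else
      min(stats::rpois(1, culling_rate), n_here - 1L)
    counts[i] <- k
    if (k > 0) keep[sample(rows, k)] <- FALSE
  }
  list(
    table = table[keep, , drop = FALSE],
    counts = data.frame(genotype = plots$genotype, block = plots$block,
                        culled_count = counts, stringsAsFactors = FALSE)
  )
}

#' Default hemp-panel simulation configuration
#'
#' Emulates the study design: 46 genotypes x 3 randomized blocks x 5 plants
#' per plot with an average of two male plants culled per plot. Twelve raw
#' traits are simulated on realistic scales (root length split over three
#' diameter classes, root and shoot dry biomass, convex hull areas, shoot
#' height, root maximum depth, crown width, lower root area, average root
#' diameter). Per-trait variance components are set so the design
#' heritability matches values of the kind reported for such panels
#' (biomass ~0.77-0.85, root length ~0.63, shoot height ~0.50), genotypic
#' coefficients of variation are ~20% (8% for root diameter), and block
#' variance is 15% of the genotypic variance. Trait correlation uses a
#' single common "plant size" factor for both the genetic and the residual
#' structure; the root-/shoot-biomass pair has genetic correlation 0.95 and
#' residual correlation 0.90, which reproduces an observed genotype-mean
#' biomass correlation near 0.93 after attenuation.
#'
#' @param seed integer seed.
#' @param culling_rate expected removals per plot; default 2.
#' @return a [trial_config()].
#' @export
default_trial_config <- function(seed = 1L, culling_rate = 2) {
  traits <- data.frame(
    name = c("root_length_diam1", "root_length_diam2", "root_length_diam3",
             "root_dry_biomass", "shoot_dry_biomass",
             "root_convex_area", "shoot_convex_area", "shoot_height",
             "root_max_depth", "root_crown_max_width", "lower_root_area",
             "avg_root_diameter"),
    mean = c(30000, 40000, 30000, 1.4, 14,
             150000, 200000, 900, 600, 300, 60000, 0.55),
    h2 = c(0.60, 0.63, 0.63, 0.85, 0.77,
           0.64, 0.66, 0.50, 0.55, 0.45, 0.51, 0.50),
    cv_g = c(0.20, 0.20, 0.20, 0.20, 0.20,
             0.20, 0.20, 0.12, 0.15, 0.15, 0.20, 0.08),
    lambda_g = c(0.85, 0.90, 0.90, 0.975, 0.975,
                 0.90, 0.90, 0.80, 0.60, 0.80, 0.85, 0.30),
    lambda_e = c(0.70, 0.75, 0.75, 0.95, 0.95,
                 0.70, 0.70, 0.60, 0.50, 0.60, 0.60, 0.10),
    stringsAsFactors = FALSE
  )
  n_blocks <- 3L; n_plants <- 5L
  sigma2_g <- (traits$cv_g * traits$mean)^2
  # design H2 = sg / (sg + se_plot / r), se_plot = se_plant / n
  sigma2_e <- n_blocks * n_plants * sigma2_g * (1 - traits$h2) / traits$h2
  sigma2_b <- 0.15 * sigma2_g
  one_factor <- function(l) { R <- l %o% l; diag(R) <- 1; R }
  trial_config(
    n_genotypes = 46L, n_blocks = n_blocks, n_plants_per_plot = n_plants,
    trait_names = traits$name, trait_means = traits$mean,
    sigma2_g = sigma2_g, sigma2_b = sigma2_b, sigma2_e = sigma2_e,
    genetic_correlation = one_factor(traits$lambda_g),
    residual_correlation = one_factor(traits$lambda_e),
    culling_rate = culling_rate, seed = seed
  )
}

# Analytic variance components of a sum of simulated traits
# (total root length = class1 + class2 + class3): each component is the sum
# of the pairwise covariances under the corresponding correlation structure;
# block effects are independent across traits so block variances just add.
sum_trait_truth <- function(config, parts, name) {
  i <- match(parts, config$trait_names)
  cov_sum <- function(s2, R) {
    sd <- sqrt(s2[i])
    sum((sd %o% sd) * R[i, i, drop = FALSE])
  }
  sg <- cov_sum(config$sigma2_g, config$genetic_correlation)
  se <- cov_sum(config$sigma2_e, config$residual_correlation)
  sb <- sum(config$sigma2_b[i])
  e_plot <- se / config$n_plants_per_plot
  data.frame(trait = name, sigma2_g = sg, sigma2_b = sb, sigma2_e = se,
             sigma2_e_plot = e_plot, r = config$n_blocks,
             H2 = sg / (sg + e_plot / config$n_blocks),
             stringsAsFactors = FALSE)
}

#' Simulate the default hemp-like panel, with culling
#'
#' Convenience wrapper: builds [default_trial_config()], simulates the trial,
#' adds `total_root_length` as the sum of the three diameter-class lengths
#' (with analytically propagated truth components), and applies male culling.
#'
#' @param seed integer seed.
#' @param culling_rate expected removals per plot; default 2.
#' @param config optional pre-built [trial_config()] overriding the default.
#' @return list: `table` (post-culling trial table), `counts` (per-plot
#'   culled counts), `truth` (per-trait true components incl. the total),
#'   `config`.
#' @export
simulate_hemp_trial <- function(seed = 1L, culling_rate = 2, config = NULL) {
  cfg <- config %||% default_trial_config(seed = seed,
                                          culling_rate = culling_rate)
  tbl <- simulate_trial(cfg)
  classes <- c("root_length_diam1", "root_length_diam2", "root_length_diam3")
  truth <- ground_truth(cfg)
  if (all(classes %in% names(tbl))) {
    tbl$total_root_length <- unname(rowSums(tbl[classes]))
    truth <- rbind(truth, sum_trait_truth(cfg, classes, "total_root_length"))
  }
  culled <- apply_culling(tbl, cfg$culling_rate, seed = cfg$seed)
  list(table = culled$table, counts = culled$counts, truth = truth,
       config = cfg)
}

#' Write / read the standard trial CSV
#'
#' Header: `genotype, block, plant, culled`, then one column per trait.
#' @param table trial table.
#' @param path file path.
#' @export
write_trial_csv <- function(table, path) {
  utils::write.csv(table, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_trial_csv
#' @export
read_trial_csv <- function(path) {
  tbl <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE)
  check_columns(tbl, c("genotype", "block", "plant", "culled"), path)
  tbl$culled <- as.logical(tbl$culled)
  tbl
}

#' Write the companion ground-truth component table
#' @param truth data.frame from [ground_truth()].
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
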