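#' Default pipeline configuration
#'
#' Declarative configuration for [run_pipeline()]. Defaults match the study
#' settings: alpha 0.05, quadrant threshold at the 50th percentile, culling
#' exclusion threshold 4, k in {3, 4}, 100 bootstrap resamples, 25 K-means
#' starts, the six-trait quadrant classification set, and the synthetic
#' hemp-panel generator as input.
#'
#' @param mode `"synthetic"` (default) or `"csv"`.
#' @param input_csv,counts_csv file paths, required in csv mode (counts
#'   optional; without them the sensitivity stage is skipped).
#' @param out_dir output directory for stage tables and the run summary.
#' @param seed integer seed used for every stochastic stage.
#' @param ... overrides for any other field (analysis_traits, root_traits,
#'   shoot_traits, alpha, quadrant_threshold, culling_threshold, k_list,
#'   B, n_starts, vc_method, vc_scale, length_unit).
#' @return a `pipeline_config` list.
#' @export
pipeline_config <- function(mode = c("synthetic", "csv"), input_csv = NULL,
                            counts_csv = NULL, out_dir = tempfile("rootshoot_"),
                            seed = 1L, ...) {
  mode <- match.arg(mode)
  cfg <- list(
    mode = mode, input_csv = input_csv, counts_csv = counts_csv,
    out_dir = out_dir, seed = as.integer(seed),
    length_unit = "mm",
    analysis_traits = c("total_root_length", "root_dry_biomass",
                        "shoot_dry_biomass", "root_convex_area",
                        "shoot_convex_area", "shoot_height",
                        "root_max_depth", "root_crown_max_width",
                        "lower_root_area", "avg_root_diameter",
                        "specific_root_length", "root_mass_fraction",
                        "lateral_root_length", "lateral_root_fraction"),
    root_traits = c("root_dry_biomass", "total_root_length",
                    "root_convex_area"),
    shoot_traits = c("shoot_dry_biomass", "shoot_convex_area",
                     "shoot_height"),
    cluster_traits = NULL,  # default: root_traits + shoot_traits
    alpha = 0.05, quadrant_threshold = 50, culling_threshold = 4,
    k_list = c(3L, 4L), B = 100L, n_starts = 25L,
    vc_method = "reml", vc_scale = "plot_mean"
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown) > 0)
    stop("unknown pipeline_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  if (mode == "csv" && (is.null(cfg$input_csv) || !file.exists(cfg$input_csv)))
    stop("csv mode requires an existing input_csv")
  if (!is.null(cfg$counts_csv) && !file.exists(cfg$counts_csv))
    stop("counts_csv does not exist: ", cfg$counts_csv)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Run the full trial analysis pipeline
#'
#' Stage order: simulate/load -> derive traits -> genotype means ->
#' variance analysis and heritability -> correlations and the two headline
#' regressions -> percentile-rank quadrant classification -> PCA, K-means,
#' bootstrap Jaccard stability and quadrant concordance -> culling
#' sensitivity (when counts are available). All stage tables are written
#' under `config$out_dir` together with a machine-readable JSON run
#' summary; identical config and seed give an identical summary.
#'
#' @param config a [pipeline_config()].
#' @return (invisibly) a list with every stage result plus `summary`.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  cfg <- config
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  log_stage <- function(name, ...) message(sprintf("[%s] ", name), ...)

  # --- input ---------------------------------------------------------------
  counts <- NULL; truth <- NULL
  if (cfg$mode == "synthetic") {
    sim <- simulate_hemp_trial(seed = cfg$seed)
    tbl <- sim$table; counts <- sim$counts; truth <- sim$truth
    write_trial_csv(tbl, file.path(cfg$out_dir, "trial.csv"))
    write_ground_truth(truth, file.path(cfg$out_dir, "ground_truth.csv"))
    utils::write.csv(counts, file.path(cfg$out_dir, "culling_counts.csv"),
                     row.names = FALSE, quote = FALSE)
  } else {
    tbl <- read_trial_csv(cfg$input_csv)
    if (!is.null(cfg$counts_csv)) {
      counts <- utils::read.csv(cfg$counts_csv, stringsAsFactors = FALSE)
      check_columns(counts, c("genotype", "block", "culled_count"),
                    cfg$counts_csv)
    }
  }
  log_stage("input", nrow(tbl), " plant records")

  # --- derive + aggregate --------------------------------------------------
  tbl <- derive_traits(tbl, length_unit = cfg$length_unit)
  traits <- intersect(cfg$analysis_traits, names(tbl))
  gm <- genotype_means(tbl, traits)
  utils::write.csv(gm, file.path(cfg$out_dir, "genotype_means.csv"),
                   row.names = FALSE, quote = FALSE)
  log_stage("derive", length(traits), " analysis traits, ",
            nrow(gm), " genotypes")

  # --- variance / heritability --------------------------------------------
  herit <- heritability_table(tbl, traits, method = cfg$vc_method,
                              scale = cfg$vc_scale)
  utils::write.csv(herit, file.path(cfg$out_dir, "heritability.csv"),
                   row.names = FALSE, quote = FALSE)
  log_stage("variance", sum(!is.na(herit$p) & herit$p < cfg$alpha),
            " traits significant at alpha=", cfg$alpha)

  # --- correlations --------------------------------------------------------
  corr <- correlation_matrix(gm, traits)
  write_correlation_result(corr, cfg$out_dir)
  regs <- list()
  if (all(c("root_dry_biomass", "shoot_dry_biomass") %in% traits))
    regs$biomass <- bivariate_regression(gm, "shoot_dry_biomass",
                                         "root_dry_biomass")
  if (all(c("shoot_dry_biomass", "root_max_depth") %in% traits))
    regs$depth <- bivariate_regression(gm, "shoot_dry_biomass",
                                       "root_max_depth")
  log_stage("correlate", "computed ", length(traits), "x", length(traits),
            " Pearson matrix")

  # --- quadrant classification --------------------------------------------
  class_traits <- union(cfg$root_traits, cfg$shoot_traits)
  pct <- percentile_ranks(gm, class_traits)
  quad <- assign_quadrants(pct, cfg$root_traits, cfg$shoot_traits,
                           threshold = cfg$quadrant_threshold)
  write_quadrant_table(quad, pct, file.path(cfg$out_dir, "quadrants.csv"))
  log_stage("classify", paste(names(table(quad$quadrant)),
                              table(quad$quadrant), sep = "=",
                              collapse = ", "))

  # --- clustering / stability / concordance --------------------------------
  cl_traits <- cfg$cluster_traits %||% class_traits
  pca <- standardize_and_pca(gm, cl_traits)
  clusters <- list()
  for (k in cfg$k_list) {
    stab <- bootstrap_jaccard(pca$scores, k = k, B = cfg$B,
                              n_starts = cfg$n_starts,
                              seed = sub_seed(cfg$seed, paste0("k", k)))
    qlab <- stats::setNames(quad$quadrant, quad$genotype)
    conc <- concordance(stab$labels, qlab)
    clusters[[as.character(k)]] <- list(stability = stab,
                                        concordance = conc)
    utils::write.csv(
      data.frame(genotype = names(stab$labels), cluster = stab$labels),
      file.path(cfg$out_dir, sprintf("clusters_k%d.csv", k)),
      row.names = FALSE, quote = FALSE)
    log_stage("cluster", "k=", k, ": Jaccard ",
              paste(round(stab$jaccard, 2), collapse = "/"),
              ", ARI vs quadrants ", round(conc$ari, 3))
  }

  # --- sensitivity ---------------------------------------------------------
  sens <- NULL
  if (!is.null(counts)) {
    filt <- filter_culled_plots(tbl, counts,
                                threshold = cfg$culling_threshold)
    herit_f <- heritability_table(filt$table, traits,
                                  method = cfg$vc_method,
                                  scale = cfg$vc_scale)
    gm_f <- genotype_means(filt$table, traits)
    sens <- compare_significance(herit, herit_f, alpha = cfg$alpha,
                                 means_full = gm, means_filtered = gm_f)
    sens$excluded_plot_fraction <- filt$excluded_fraction
    log_stage("sensitivity", round(100 * filt$excluded_fraction, 1),
              "% of plots excluded; lost=",
              paste(sens$traits_lost_significance, collapse = ","),
              " gained=",
              paste(sens$traits_gained_significance, collapse = ","))
  }

  # --- summary -------------------------------------------------------------
  summary <- list(
    package_version = as.character(utils::packageVersion("rootshoot")),
    seed = cfg$seed, mode = cfg$mode,
    config = cfg[setdiff(names(cfg), c("out_dir"))],
    n_plants = nrow(tbl), n_genotypes = nrow(gm),
    heritability = stats::setNames(herit$H2, herit$trait),
    significant_traits = herit$trait[!is.na(herit$p) & herit$p < cfg$alpha],
    regressions = regs,
    quadrant_counts = as.list(table(quad$quadrant)),
    pca_variance_explained = pca$variance_explained,
    cluster_jaccard = lapply(clusters, function(x) x$stability$jaccard),
    cluster_ari = lapply(clusters, function(x) x$concordance$ari),
    sensitivity = if (is.null(sens)) NULL else list(
      excluded_plot_fraction = sens$excluded_plot_fraction,
      lost = sens$traits_lost_significance,
      gained = sens$traits_gained_significance)
  )
  jsonlite::write_json(summary, file.path(cfg$out_dir, "run_summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       force = TRUE)
  invisible(list(table = tbl, genotype_means = gm, heritability = herit,
                 correlation = corr, regressions = regs, percentiles = pct,
                 quadrants = quad, pca = pca, clusters = clusters,
                 sensitivity = sens, truth = truth, summary = summary))
}
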