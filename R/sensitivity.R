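#' Exclude heavily culled plots from a trial table
#'
#' Removes every genotype-by-block plot whose culled count reaches the
#' threshold (default 4 removed plants of 5 sown) and reports the excluded
#' plot fraction. Counts come from the simulator's truth table or a
#' user-supplied per-plot count file; culling is never inferred from
#' missingness.
#'
#' @param table trial table.
#' @param counts data.frame with columns genotype, block, culled_count.
#' @param threshold minimum culled count for exclusion; must be >= 1.
#' @return list: `table` (filtered), `excluded_fraction` (of plots in
#'   `counts`), `excluded_plots` (the removed genotype/block pairs).
#' @export
filter_culled_plots <- function(table, counts, threshold = 4) {
  if (threshold < 1) stop("threshold must be >= 1")
  check_columns(counts, c("genotype", "block", "culled_count"),
                "culling counts")
  check_columns(table, c("genotype", "block"), "trial table")
  bad <- counts[counts$culled_count >= threshold, c("genotype", "block"),
                drop = FALSE]
  key <- function(g, b) paste(g, b, sep = "\r")
  drop_rows <- key(table$genotype, table$block) %in% key(bad$genotype,
                                                         bad$block)
  list(table = table[!drop_rows, , drop = FALSE],
       excluded_fraction = nrow(bad) / nrow(counts),
       excluded_plots = bad)
}

#' Compare per-trait significance before and after plot exclusion
#'
#' Classifies each trait by whether the genotype-effect p-value crosses
#' `alpha` between the full and filtered analyses, and reports per-trait
#' heritability shifts plus (when genotype means are supplied) the
#' Spearman correlation of genotype rankings before vs after.
#'
#' @param full,filtered [heritability_table()] results over the same
#'   traits.
#' @param alpha significance level, default 0.05 (uncorrected, matching
#'   per-trait reporting).
#' @param means_full,means_filtered optional genotype-mean tables
#'   ([genotype_means()]) for the ranking correlation.
#' @return list of class `sensitivity_report`: `excluded_plot_fraction`
#'   (NA unless set by the caller), `traits_lost_significance`,
#'   `traits_gained_significance`, `status` (per-trait classification),
#'   `heritability_shift`, `ranking_correlation`.
#' @export
compare_significance <- function(full, filtered, alpha = 0.05,
                                 means_full = NULL, means_filtered = NULL) {
  if (!setequal(full$trait, filtered$trait)) {
    stop("trait lists differ: ",
         paste(union(setdiff(full$trait, filtered$trait),
                     setdiff(filtered$trait, full$trait)), collapse = ", "))
  }
  filtered <- filtered[match(full$trait, filtered$trait), , drop = FALSE]
  sig_full <- !is.na(full$p) & full$p < alpha
  sig_filt <- !is.na(filtered$p) & filtered$p < alpha
  status <- ifelse(sig_full & sig_filt, "stable-significant",
            ifelse(!sig_full & !sig_filt, "stable-nonsignificant",
            ifelse(sig_full & !sig_filt, "lost", "gained")))
  shift <- data.frame(trait = full$trait,
                      H2_full = full$H2, H2_filtered = filtered$H2,
                      delta_H2 = filtered$H2 - full$H2,
                      stringsAsFactors = FALSE)
  ranking <- NULL
  if (!is.null(means_full) && !is.null(means_filtered)) {
    shared <- intersect(means_full$genotype, means_filtered$genotype)
    ranking <- vapply(full$trait, function(tr) {
      if (!tr %in% names(means_full) || !tr %in% names(means_filtered))
        return(NA_real_)
      a <- means_full[[tr]][match(shared, means_full$genotype)]
      b <- means_filtered[[tr]][match(shared, means_filtered$genotype)]
      ok <- !is.na(a) & !is.na(b)
      if (sum(ok) < 3) return(NA_real_)
      stats::cor(a[ok], b[ok], method = "spearman")
    }, numeric(1))
  }
  structure(list(
    excluded_plot_fraction = NA_real_,
    traits_lost_significance = full$trait[status == "lost"],
    traits_gained_significance = full$trait[status == "gained"],
    status = stats::setNames(status, full$trait),
    heritability_shift = shift,
    ranking_correlation = ranking,
    alpha = alpha), class = "sensitivity_report")
}
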