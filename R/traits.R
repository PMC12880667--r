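#' Compute derived root and shoot traits per plant
#'
#' Appends the standard derived traits to a trial table:
#' \describe{
#'   \item{specific_root_length}{total root length / root dry biomass, in
#'     m g^-1 (lengths are converted from the declared unit to metres).
#'     High SRL indicates thin, metabolically cheap roots.}
#'   \item{root_mass_fraction}{root dry biomass / (root + shoot dry
#'     biomass), a biomass-allocation index in [0, 1].}
#'   \item{lateral_root_length}{sum of root length in the finer diameter
#'     classes (scanner classes 2 and 3), same unit as the input lengths.}
#'   \item{lateral_root_fraction}{lateral root length / total root length,
#'     in [0, 1].}
#'   \item{total_biomass}{root + shoot dry biomass (g).}
#'   \item{root_shoot_ratio}{root dry biomass / shoot dry biomass.}
#' }
#' Rows with missing or zero denominators yield missing derived values,
#' never errors. Re-running simply recomputes the derived columns
#' (idempotent).
#'
#' @param table trial table with raw measurement columns.
#' @param length_unit unit of the raw length columns: `"mm"` (scanner
#'   convention, default) or `"m"`.
#' @param col_map optional named character vector mapping the canonical raw
#'   names (`total_root_length`, `root_length_diam2`, `root_length_diam3`,
#'   `root_dry_biomass`, `shoot_dry_biomass`) to the column names actually
#'   present, e.g. for RhizoVision Explorer export headers.
#' @return `table` with the six derived columns appended/recomputed.
#' @export
derive_traits <- function(table, length_unit = c("mm", "m"), col_map = NULL) {
  length_unit <- match.arg(length_unit)
  canonical <- c("total_root_length", "root_length_diam2",
                 "root_length_diam3", "root_dry_biomass",
                 "shoot_dry_biomass")
  cols <- stats::setNames(canonical, canonical)
  if (!is.null(col_map)) cols[names(col_map)] <- col_map
  check_columns(table, unname(cols), "trial table")

  to_m <- if (length_unit == "mm") 1 / 1000 else 1
  trl <- table[[cols["total_root_length"]]]
  d2 <- table[[cols["root_length_diam2"]]]
  d3 <- table[[cols["root_length_diam3"]]]
  rdb <- table[[cols["root_dry_biomass"]]]
  sdb <- table[[cols["shoot_dry_biomass"]]]

  table$specific_root_length <- safe_div(trl * to_m, rdb)
  table$root_mass_fraction <- safe_div(rdb, rdb + sdb)
  table$lateral_root_length <- d2 + d3
  table$lateral_root_fraction <- safe_div(d2 + d3, trl)
  table$total_biomass <- rdb + sdb
  table$root_shoot_ratio <- safe_div(rdb, sdb)
  table
}

#' Genotype-level trait means
#'
#' Arithmetic mean per genotype over all non-missing, non-culled plants
#' pooled across blocks (robust to unequal plot sizes after culling), with
#' per-cell sample sizes. Optionally averages block means instead.
#'
#' @param table trial table (raw and/or derived columns).
#' @param traits character vector of trait columns to aggregate.
#' @param by_block if TRUE, aggregate to block means first and average
#'   those (means-of-block-means); default FALSE (pooled plants).
#' @return data.frame `genotype` plus one column per trait; attribute
#'   `"n"` is the matching genotype x trait matrix of sample sizes
#'   (in `by_block` mode, the number of contributing plants).
#' @export
genotype_means <- function(table, traits, by_block = FALSE) {
  if (nrow(table) == 0) stop("trial table is empty")
  check_columns(table, c("genotype", traits), "trial table")
  if ("culled" %in% names(table)) {
    table <- table[!isTRUE_vec(table$culled), , drop = FALSE]
  }
  genos <- sort(unique(table$genotype))
  mean_na <- function(v) if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  agg <- function(trait) {
    v <- table[[trait]]
    if (by_block) {
      bm <- tapply(v, list(table$genotype, table$block), mean_na)
      vals <- rowMeans(bm, na.rm = TRUE)[genos]
      vals[is.nan(vals)] <- NA_real_
    } else {
      vals <- tapply(v, table$genotype, mean_na)[genos]
    }
    n <- tapply(!is.na(v), table$genotype, sum)[genos]
    n[is.na(n)] <- 0L
    list(mean = as.vector(vals), n = as.vector(n))
  }
  parts <- lapply(traits, agg)
  out <- data.frame(genotype = genos, stringsAsFactors = FALSE)
  for (i in seq_along(traits)) out[[traits[i]]] <- parts[[i]]$mean
  n_mat <- do.call(cbind, lapply(parts, `[[`, "n"))
  dimnames(n_mat) <- list(genos, traits)
  attr(out, "n") <- n_mat
  empty <- colSums(n_mat) == 0
  if (any(empty)) {
    message("genotype_means: trait(s) with no observations: ",
            paste(traits[empty], collapse = ", "))
  }
  out
}

# TRUE only where x is TRUE (NA treated as FALSE).
isTRUE_vec <- function(x) !is.na(x) & x
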