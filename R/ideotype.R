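#' Percentile ranks of genotypes per trait
#'
#' Rank-based percentiles: `100 * rank / n` with average ranks for ties,
#' computed over the non-missing genotypes of each trait. Invariant to any
#' strictly increasing transform of the trait. (With fewer genotypes than
#' 100, quantile binning into 100 bins degenerates to a pure ranking, which
#' is what this implements directly.)
#'
#' @param data data.frame of genotype means with a `genotype` column.
#' @param traits character vector of trait columns.
#' @return data.frame `genotype` plus one percentile column per trait
#'   (values in (0, 100]). All-missing traits are excluded with a message.
#' @export
percentile_ranks <- function(data, traits) {
  check_columns(data, c("genotype", traits), "data")
  keep <- traits[vapply(traits, function(tr) any(!is.na(data[[tr]])),
                        logical(1))]
  if (length(keep) < length(traits)) {
    message("percentile_ranks: excluding all-missing trait(s): ",
            paste(setdiff(traits, keep), collapse = ", "))
  }
  out <- data.frame(genotype = data$genotype, stringsAsFactors = FALSE)
  for (tr in keep) {
    v <- data[[tr]]
    n <- sum(!is.na(v))
    if (n < 2) stop("percentile_ranks: trait '", tr,
                    "' has fewer than 2 non-missing genotypes")
    out[[tr]] <- 100 * rank(v, ties.method = "average", na.last = "keep") / n
  }
  out
}

#' Assign genotypes to root-shoot quadrant ideotypes
#'
#' A genotype's root status is BIG when its percentile exceeds `threshold`
#' for every root trait, SMALL when at or below `threshold` for every root
#' trait, and MIXED otherwise; likewise for the shoot status. Quadrants:
#' I = big root / big shoot, II = big root / small shoot, III = small root /
#' small shoot, IV = small root / big shoot; any MIXED status (or a missing
#' classification trait) leaves the genotype UNASSIGNED, with the nearest
#' group recorded via [nearest_group()].
#'
#' @param percentiles percentile table from [percentile_ranks()].
#' @param root_traits,shoot_traits nonempty, disjoint character vectors of
#'   trait columns. Defaults are the six-trait set: root dry biomass, total
#'   root length and root convex area vs shoot dry biomass, shoot convex
#'   area and shoot height.
#' @param threshold percentile cutoff, default 50 ("upper 50%" is strictly
#'   greater than the threshold).
#' @return data.frame per genotype: genotype, root_status, shoot_status,
#'   quadrant (I/II/III/IV/UNASSIGNED), resembles (I/II/III/IV/NONE),
#'   missing_data flag. Trait sets and threshold are attached as the
#'   `"classification"` attribute.
#' @export
assign_quadrants <- function(percentiles,
                             root_traits = c("root_dry_biomass",
                                             "total_root_length",
                                             "root_convex_area"),
                             shoot_traits = c("shoot_dry_biomass",
                                              "shoot_convex_area",
                                              "shoot_height"),
                             threshold = 50) {
  stopifnot(length(root_traits) > 0, length(shoot_traits) > 0)
  if (length(intersect(root_traits, shoot_traits)) > 0)
    stop("root_traits and shoot_traits must be disjoint")
  check_columns(percentiles, c("genotype", root_traits, shoot_traits),
                "percentile table")

  status_of <- function(p) {
    if (any(is.na(p))) return(NA_character_)
    if (all(p > threshold)) "BIG"
    else if (all(p <= threshold)) "SMALL"
    else "MIXED"
  }
  quadrant_of <- function(rs, ss) {
    if (is.na(rs) || is.na(ss) || rs == "MIXED" || ss == "MIXED")
      return("UNASSIGNED")
    if (rs == "BIG" && ss == "BIG") "I"
    else if (rs == "BIG") "II"
    else if (ss == "BIG") "IV"
    else "III"
  }

  rmat <- as.matrix(percentiles[root_traits])
  smat <- as.matrix(percentiles[shoot_traits])
  n <- nrow(percentiles)
  root_status <- character(n); shoot_status <- character(n)
  quadrant <- character(n); resembles <- character(n)
  missing_data <- logical(n)
  for (i in seq_len(n)) {
    root_status[i] <- status_of(rmat[i, ])
    shoot_status[i] <- status_of(smat[i, ])
    missing_data[i] <- is.na(root_status[i]) || is.na(shoot_status[i])
    quadrant[i] <- quadrant_of(root_status[i], shoot_status[i])
    resembles[i] <- if (quadrant[i] == "UNASSIGNED") {
      nearest_group(rmat[i, ], smat[i, ], threshold)
    } else "NONE"
  }
  out <- data.frame(genotype = percentiles$genotype,
                    root_status = ifelse(is.na(root_status), "MIXED",
                                         root_status),
                    shoot_status = ifelse(is.na(shoot_status), "MIXED",
                                          shoot_status),
                    quadrant = quadrant, resembles = resembles,
                    missing_data = missing_data, stringsAsFactors = FALSE)
  attr(out, "classification") <- list(root_traits = root_traits,
                                      shoot_traits = shoot_traits,
                                      threshold = threshold)
  out
}

#' Nearest quadrant group for an unassigned genotype
#'
#' Each side (root, shoot) is summarized by the majority of its per-trait
#' big/small indicators; a tie is broken by the sign of the mean deviation
#' of the side's percentiles from the threshold. The resulting big/small
#' pair maps to the quadrant the genotype most resembles.
#'
#' @param root_pct,shoot_pct numeric percentile vectors for the root and
#'   shoot classification traits of one genotype (NAs ignored).
#' @param threshold percentile cutoff, default 50.
#' @return one of "I", "II", "III", "IV" ("NONE" if a whole side is
#'   missing).
#' @export
nearest_group <- function(root_pct, shoot_pct, threshold = 50) {
  side <- function(p) {
    p <- p[!is.na(p)]
    if (length(p) == 0) return(NA)
    big <- sum(p > threshold); small <- sum(p <= threshold)
    if (big != small) big > small else mean(p) - threshold > 0
  }
  rb <- side(root_pct); sb <- side(shoot_pct)
  if (is.na(rb) || is.na(sb)) return("NONE")
  if (rb && sb) "I" else if (rb) "II" else if (sb) "IV" else "III"
}

#' Write the per-genotype assignment table
#' @param assignment result of [assign_quadrants()].
#' @param percentiles matching [percentile_ranks()] table.
#' @param path output CSV path.
#' @export
write_quadrant_table <- function(assignment, percentiles, path) {
  merged <- merge(percentiles, assignment, by = "genotype", sort = TRUE)
  utils::write.csv(merged, path, row.names = FALSE, quote = FALSE)
  invisible(merged)
}
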