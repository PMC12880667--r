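#' Standardize genotype means and run PCA
#'
#' Column-wise z-scores (mean-centered and scaled) followed by principal
#' component analysis of the standardized matrix, i.e. an
#' eigendecomposition of the trait correlation structure. Deterministic up
#' to component sign. Genotypes with any missing cell are dropped with a
#' message, as are constant traits.
#'
#' @param data data.frame of genotype means with a `genotype` column.
#' @param traits character vector of trait columns.
#' @return list of class `pca_result`: `scores` (genotype x component),
#'   `loadings` (trait x component), `variance_explained` (fractions,
#'   nonincreasing), `z` (the standardized matrix), `genotypes`, `traits`,
#'   `dropped_genotypes`, `dropped_traits`.
#' @export
standardize_and_pca <- function(data, traits) {
  check_columns(data, c("genotype", traits), "data")
  x <- as.matrix(data[traits])
  rownames(x) <- data$genotype
  const <- apply(x, 2, function(v) stats::var(v, na.rm = TRUE) == 0)
  const[is.na(const)] <- TRUE
  if (any(const)) {
    message("standardize_and_pca: dropping constant trait(s): ",
            paste(traits[const], collapse = ", "))
    x <- x[, !const, drop = FALSE]
  }
  complete <- stats::complete.cases(x)
  if (any(!complete)) {
    message("standardize_and_pca: dropping genotype(s) with missing cells: ",
            paste(rownames(x)[!complete], collapse = ", "))
    x <- x[complete, , drop = FALSE]
  }
  if (nrow(x) < 3 || ncol(x) < 2)
    stop("need >= 3 complete genotypes and >= 2 non-constant traits")
  z <- scale(x)
  attr(z, "scaled:center") <- NULL; attr(z, "scaled:scale") <- NULL
  pc <- stats::prcomp(z, center = FALSE, scale. = FALSE)
  ve <- pc$sdev^2 / sum(pc$sdev^2)
  structure(list(scores = pc$x, loadings = pc$rotation,
                 variance_explained = ve, z = z,
                 genotypes = rownames(x), traits = colnames(x),
                 dropped_genotypes = data$genotype[!data$genotype %in%
                                                     rownames(x)],
                 dropped_traits = traits[const]),
            class = "pca_result")
}

#' K-means clustering with multiple random starts
#'
#' Best of `n_starts` random initializations by total within-cluster sum
#' of squares; deterministic for a fixed seed. Empty-cluster failures are
#' retried with fresh starts.
#'
#' @param x numeric matrix (rows = genotypes).
#' @param k number of clusters, `2 <= k <= nrow(x) - 1` (and no more than
#'   the number of distinct rows).
#' @param n_starts random initializations, default 25.
#' @param seed integer seed.
#' @return list: `labels` (named integer vector), `tot_withinss`, `k`,
#'   `centers`.
#' @export
kmeans_cluster <- function(x, k, n_starts = 25, seed = 1L) {
  x <- as.matrix(x)
  n_distinct <- nrow(unique(x))
  if (k < 2) stop("k must be >= 2")
  if (k > n_distinct) stop("k exceeds the number of distinct points")
  if (k == n_distinct) {
    # exact optimum: every distinct point is a center, WCSS = 0
    centers <- unique(x)
    row_key <- function(m) apply(m, 1, paste, collapse = "\r")
    labels <- match(row_key(x), row_key(centers))
    names(labels) <- rownames(x)
    return(list(labels = labels, tot_withinss = 0, k = k,
                centers = centers))
  }
  set.seed(seed)
  fit <- NULL
  for (attempt in 1:5) {
    fit <- tryCatch(
      suppressWarnings(stats::kmeans(x, centers = k, nstart = n_starts,
                                     iter.max = 100)),
      error = function(e) NULL)
    if (!is.null(fit)) break
  }
  if (is.null(fit)) stop("kmeans failed to produce ", k, " clusters")
  labels <- fit$cluster
  names(labels) <- rownames(x)
  list(labels = labels, tot_withinss = fit$tot.withinss, k = k,
       centers = fit$centers)
}

# Jaccard similarity of two index sets.
jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Bootstrap Jaccard stability of K-means clusters
#'
#' For each of `B` bootstrap resamples (rows drawn with replacement), the
#' resample is re-clustered from fresh random starts (the original solution
#' is never reused as initialization). Each original cluster, restricted to
#' the points present in the resample, is matched to the bootstrap cluster
#' maximizing the Jaccard similarity; its stability is the mean of those
#' maxima over resamples. Resamples where the maximum falls below 0.5 count
#' as dissolutions but still contribute their value to the mean.
#'
#' @param x numeric matrix (rows = genotypes).
#' @param k number of clusters.
#' @param B bootstrap resamples, at least 20 (default 100).
#' @param n_starts K-means random starts per clustering, default 25.
#' @param seed integer seed.
#' @return list of class `cluster_stability`: `labels` (original
#'   clustering), `jaccard` (per-cluster mean stability), `dissolved`
#'   (per-cluster dissolution counts), `B`, `k`, `seed`.
#' @export
bootstrap_jaccard <- function(x, k, B = 100, n_starts = 25, seed = 1L) {
  if (B < 20) stop("B must be >= 20")
  x <- as.matrix(x)
  n <- nrow(x)
  orig <- kmeans_cluster(x, k, n_starts = n_starts,
                         seed = sub_seed(seed, "kmeans-original"))
  orig_sets <- split(seq_len(n), orig$labels)
  sums <- numeric(k); counts <- integer(k); dissolved <- integer(k)
  set.seed(sub_seed(seed, "bootstrap"))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    present <- unique(idx)
    boot_seed <- sample.int(.Machine$integer.max, 1)
    fit_b <- tryCatch(
      kmeans_cluster(x[idx, , drop = FALSE], k, n_starts = n_starts,
                     seed = boot_seed),
      error = function(e) NULL)
    if (is.null(fit_b)) next  # e.g. resample with fewer distinct points than k
    # label each unique original index by its bootstrap cluster (duplicated
    # rows are identical points, so their assignments agree)
    lab_by_orig <- fit_b$labels[match(present, idx)]
    boot_sets <- split(present, lab_by_orig)
    for (cl in seq_len(k)) {
      a <- intersect(orig_sets[[cl]], present)
      counts[cl] <- counts[cl] + 1L
      if (length(a) == 0) { dissolved[cl] <- dissolved[cl] + 1L; next }
      jmax <- max(vapply(boot_sets, jaccard, numeric(1), a = a))
      sums[cl] <- sums[cl] + jmax
      if (jmax < 0.5) dissolved[cl] <- dissolved[cl] + 1L
    }
  }
  stab <- ifelse(counts > 0, sums / counts, NA_real_)
  if (any(dissolved > 0.5 * B)) {
    message("bootstrap_jaccard: cluster(s) dissolved in >50% of resamples: ",
            paste(which(dissolved > 0.5 * B), collapse = ", "))
  }
  structure(list(labels = orig$labels, jaccard = stab,
                 dissolved = dissolved, B = B, k = k, seed = seed),
            class = "cluster_stability")
}

#' Adjusted Rand index between two labelings
#'
#' Chance-corrected agreement from the contingency-table closed form:
#' with `n_ij` the cross-tabulation, `ARI = (sum_ij C(n_ij,2) - E) /
#' (max - E)` where `E = sum_i C(a_i,2) sum_j C(b_j,2) / C(n,2)`.
#' Returns 1 for two identical partitions; defined as 1 when both
#' partitions are single clusters.
#'
#' @param a,b label vectors over the same items.
#' @return ARI in [-1, 1].
#' @export
adjusted_rand_index <- function(a, b) {
  stopifnot(length(a) == length(b))
  keep <- !is.na(a) & !is.na(b)
  a <- a[keep]; b <- b[keep]
  n <- length(a)
  if (n < 2) return(NA_real_)
  tab <- table(a, b)
  comb2 <- function(m) m * (m - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  expected <- sum_a * sum_b / comb2(n)
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)
  (sum_ij - expected) / (max_index - expected)
}

#' Concordance between cluster labels and quadrant groups
#'
#' @param cluster_labels named vector (names = genotypes) of cluster ids.
#' @param quadrant_labels named vector (names = genotypes) of quadrant
#'   labels; the comparison uses the shared genotype set.
#' @return list of class `concordance_result`: `table` (cluster x
#'   quadrant contingency table), `ari`, `n`.
#' @export
concordance <- function(cluster_labels, quadrant_labels) {
  shared <- intersect(names(cluster_labels), names(quadrant_labels))
  if (length(shared) == 0) stop("no shared genotypes between labelings")
  cl <- cluster_labels[shared]; qd <- quadrant_labels[shared]
  structure(list(table = table(cluster = cl, quadrant = qd),
                 ari = adjusted_rand_index(cl, qd), n = length(shared)),
            class = "concordance_result")
}
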