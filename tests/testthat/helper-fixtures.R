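# Shared fixtures and independent oracles for the test suite.

# Minimal single-trait configuration for Monte Carlo work.
one_trait_config <- function(sigma2_g = 1, sigma2_b = 0.15, sigma2_e = 3,
                             n_genotypes = 46, n_blocks = 3, n_plants = 5,
                             culling_rate = 0, seed = 1, mean = 100) {
  trial_config(n_genotypes, n_blocks, n_plants, "y", mean,
               sigma2_g, sigma2_b, sigma2_e,
               culling_rate = culling_rate, seed = seed)
}

# Variance components hitting a target design heritability
# H2 = sg / (sg + (se / n) / r) with sg = 1.
config_for_h2 <- function(h2, n_genotypes = 46, n_blocks = 3, n_plants = 5,
                          seed = 1) {
  se <- n_blocks * n_plants * (1 - h2) / h2
  one_trait_config(sigma2_g = 1, sigma2_b = 0.15, sigma2_e = se,
                   n_genotypes = n_genotypes, n_blocks = n_blocks,
                   n_plants = n_plants, seed = seed)
}

# Eight-genotype genotype-mean table with a hand-derived quadrant structure.
# Three root traits (r1-r3) and three shoot traits (s1-s3); ties are used so
# that traits can have unequal big/small group sizes. Ranks of 8 give
# percentiles in steps of 12.5; tied groups take the average rank.
# Hand-derived expectation (genotypes A-H in order):
#   quadrant  = I, I, II, III, III, IV, UNASSIGNED, UNASSIGNED
#   resembles = NONE x6, IV (G: root 1 big / 2 small, shoot all big),
#               III (H: root all small, shoot 1 big / 2 small)
quadrant_fixture <- function() {
  data.frame(
    genotype = LETTERS[1:8],
    r1 = c(100, 90, 80, 10, 9, 8, 70, 7),
    r2 = c(100, 90, 80, 10, 10, 10, 10, 10),
    r3 = c(100, 90, 80, 10, 10, 10, 10, 10),
    s1 = c(100, 100, 30, 20, 10, 100, 100, 100),
    s2 = c(100, 90, 40, 30, 20, 80, 70, 10),
    s3 = c(100, 90, 40, 30, 20, 80, 70, 10),
    stringsAsFactors = FALSE
  )
}

quadrant_fixture_expected <- function() {
  list(quadrant = c(A = "I", B = "I", C = "II", D = "III", E = "III",
                    F = "IV", G = "UNASSIGNED", H = "UNASSIGNED"),
       resembles = c(A = "NONE", B = "NONE", C = "NONE", D = "NONE",
                     E = "NONE", F = "NONE", G = "IV", H = "III"))
}

# Brute-force adjusted Rand index by explicit enumeration of all item
# pairs, independent of the contingency-table closed form.
ari_bruteforce <- function(a, b) {
  n <- length(a)
  n11 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sa <- a[i] == a[j]; sb <- b[i] == b[j]
      if (sa && sb) n11 <- n11 + 1
      else if (sa) n10 <- n10 + 1
      else if (sb) n01 <- n01 + 1
    }
  }
  total <- n * (n - 1) / 2
  expected <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == expected) return(1)
  (n11 - expected) / (max_index - expected)
}

# Three well-separated spherical Gaussian clusters in 2D.
gaussian_clusters <- function(n_per = 20, sep = 10, sd = 1, seed = 1) {
  set.seed(seed)
  centers <- rbind(c(0, 0), c(sep, 0), c(0, sep))
  x <- do.call(rbind, lapply(1:3, function(i) {
    cbind(rnorm(n_per, centers[i, 1], sd), rnorm(n_per, centers[i, 2], sd))
  }))
  list(x = x, labels = rep(1:3, each = n_per))
}
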