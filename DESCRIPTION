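Package: rootshoot
Title: Root-Shoot Phenomics Trial Analysis with Heritability, Ideotype
    Classification and Cluster Stability
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Analysis pipeline for randomized-block root and shoot
    phenotyping trials, motivated by image-based root system architecture
    panels in industrial hemp. Computes derived traits (specific root
    length, root mass fraction, lateral root length and fraction), fits
    per-trait genotype-by-block mixed models to estimate variance
    components and broad-sense heritability, builds pairwise-complete
    Pearson correlation structure over genotype means, classifies
    genotypes into root-shoot quadrant ideotypes by percentile rank,
    assesses K-means cluster stability with bootstrap Jaccard similarity
    and concordance with quadrant groups, and re-runs the analyses after
    excluding heavily culled plots as a sensitivity check. Includes a
    synthetic trial generator with known variance components, genetic and
    residual trait correlations, and male-culling missingness so the whole
    pipeline is testable without the deposited trial data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
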