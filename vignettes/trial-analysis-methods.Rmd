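---
title: "Methods: root-shoot trial analysis, heritability and ideotype classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: root-shoot trial analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rootshoot)
```

## The problem and the model

`rootshoot` analyzes randomized-block phenotyping trials of the kind used to
characterize root system architecture panels: a set of genotypes, each grown
as several plants in each of a few replicate blocks, with per-plant root and
shoot measurements extracted from images and biomass weights. The per-plant
model for every trait is the additive two-way random layout

y_ijk = mu + g_i + b_j + e_ijk,

with genotype effects g_i, block effects b_j and plant residuals e_ijk.
Everything downstream — heritability, correlations, ideotype quadrants,
cluster stability, the culling sensitivity check — is a function of this
table.

## Derived traits

From the raw columns the package computes specific root length
(total root length / root dry biomass, reported in m g^-1 after converting
lengths from the declared unit, mm by default, to metres), root mass
fraction (root / (root + shoot) dry biomass), lateral root length (sum of
the two finer diameter-class lengths), lateral root fraction (lateral /
total length), total biomass, and the root:shoot biomass ratio. Rows with
missing or zero denominators propagate missing values rather than failing:
a plant with no recovered root system should not abort a panel analysis.
The diameter-class boundaries themselves are taken as given from the
upstream image analysis; the pipeline never re-bins lengths.

Genotype means pool all surviving, non-missing plants across blocks rather
than averaging block means. Pooling is robust to unequal plot sizes after
culling; a means-of-block-means option (`by_block = TRUE`) is provided for
comparison since the two differ exactly when plots are unbalanced.

## Variance analysis and heritability

Two model fits serve two purposes:

* **Significance.** The genotype effect is tested with genotype fixed and
  block random (`lme4::lmer(y ~ genotype + (1|block))`), with an F statistic
  on `G - 1` and `N - G - B + 1` (between-within) denominator degrees of
  freedom — exact for balanced layouts, a good approximation at the mild
  unbalance culling produces. A 1000-replicate null simulation at the
  design size with culling keeps the empirical size within [0.03, 0.07]
  at alpha = 0.05.
* **Components.** Heritability needs a genotypic *variance*, so components
  are estimated from a second fit with genotype random. The default REML
  fit operates on genotype-by-block plot means, making the residual a
  plot-mean residual, and

  H^2 = sigma2_g / (sigma2_g + sigma2_e / r)

  with `r` the number of replicate blocks is then the repeatability of a
  genotype mean over `r` full plots. The alternative — plant-level residual
  divided by `r` only — conflates plot size with replication; the plant
  scale remains available via `scale = "plant"`.

The closed-form expected-mean-squares (EMS) solution
(`sigma2_g = (MS_G - MS_E)/r` on plot means) is kept as an independent
estimator: on balanced data REML and EMS coincide, and the test suite
verifies agreement to 1e-6 relative across random balanced datasets. The
REML optimizer (bobyqa) runs at a tightened stopping tolerance (`rhoend`
2e-13) so that this equivalence is measured against the estimator, not the
optimizer. In the comparison, relative differences for components estimated
at essentially zero (absolute REML-EMS gaps near machine precision) are
scaled by 1% of the total variance instead of the component itself, which
would otherwise make the ratio ill-conditioned. Negative EMS solutions are
truncated to zero and flagged; REML is bounded at zero by construction and
the flag records boundary estimates. No multiple-testing correction is
applied across traits by default (per-trait p < 0.05 reporting); a
Benjamini-Hochberg column is available via `adjust_p = "BH"`.

## Correlation structure

Pearson correlations are computed on pairwise-complete observations over
genotype means (the analysis level is recorded in the result object;
plant-level is available by passing a plant table). P-values come from the
t transform `t = r sqrt((n-2)/(1-r^2))` at the pairwise-complete `n`;
pairs with fewer than three complete observations and zero-variance traits
are reported missing with diagnostics. Genotype means are the default level
because panel-scale trait relationships are genotype-level claims; with a
complete design the shared block effects cancel out of genotype means, so
those correlations reflect genetic plus mean-residual covariance.

## Quadrant ideotypes

For classification each trait is converted to a percentile rank,
`100 * rank / n` with average ranks for ties — with panels far smaller than
100 genotypes, binning into 100 quantiles degenerates to exactly this
ranking, so the rank form is used directly and documented as such. A
genotype is "big-rooted" when it exceeds the 50th percentile on *every*
root classification trait, "small-rooted" when at or below it on every one,
and mixed otherwise; likewise for shoots. The four quadrants are big/big
(I), big root/small shoot (II), small/small (III) and small root/big shoot
(IV); any mixed side leaves the genotype unassigned. The default
classification set is the six-trait one (root dry biomass, total root
length, root convex area; shoot dry biomass, shoot convex area, shoot
height); a five-trait variant (dropping shoot height) can be selected by
passing different trait sets, and the sets used are recorded in the
result's metadata. Unassigned genotypes get a nearest-group label: each
side is summarized by the majority of its big/small indicators, ties broken
by the sign of the mean percentile deviation from the threshold. Percentile
ranks are invariant to monotone trait transforms, so centering/scaling
choices affect only visualization and clustering, never the classification.

## PCA, K-means and stability

Clustering operates on the full set of principal-component scores of the
z-scored genotype-by-trait matrix — equivalent to clustering the scaled
data itself, since keeping all components is a rotation; the score form
makes truncation available when wanted. K-means uses 25 random starts
(best by within-cluster sum of squares) and is deterministic given the
seed. Cluster stability is assessed by bootstrap Jaccard similarity:
for each of B = 100 resamples drawn with replacement, the resample is
re-clustered from fresh random starts (never seeded with the original
solution, which would bias stability upward), each original cluster is
restricted to the points present in the resample and matched to the
bootstrap cluster of maximal Jaccard overlap, and the per-cluster
stability is the mean of those maxima. Resamples where the maximum falls
below 0.5 count as dissolutions and still contribute their value; the
dissolution count is reported alongside. Concordance between cluster and
quadrant labels is the adjusted Rand index from the contingency-table
closed form, verified in the tests against brute-force pair counting.

## The synthetic panel

The generator exists so that every stage is testable with known truth. Its
default configuration is the study design: 46 genotypes x 3 blocks x 5
plants, average culling of two plants per plot. Per-trait variance
components are set from (i) a genotypic CV of ~20% (8% for root diameter),
matching panels where extreme genotype means differ by ~2.5x, and (ii)
design heritabilities in the 0.45-0.85 range typical of such trials
(biomass highest, crown width lowest). Trait correlation uses a
single common "plant size" factor for both genetic effects and residuals.
The factor loadings give the root/shoot biomass pair a genetic correlation
of 0.95 and a residual correlation of 0.90: an observed genotype-mean
biomass correlation near 0.93 *cannot* arise from a genetic correlation
alone once genotype means are attenuated by reliabilities near 0.8, so a
within-plant vigor correlation is a structural requirement of realistic
panels, not a tuning knob. Root length is simulated per diameter class and
totalled, which makes lateral length structurally no greater than total
length. Culling removes `min(Poisson(rate), n-1)` plants per plot —
guaranteeing a survivor — independently of trait values; whether real male
plants differ in traits before removal is unknowable from a
female-only harvest, so the simulator makes the neutral choice. Normal
draws are clamped at zero for lengths, masses and areas; with the default
means this affects a vanishing fraction of values (4+ standard deviations
from the mean) and leaves recovery tests unbiased at their tolerances.

What the generator does not emulate: spatial/neighbor effects within
blocks (including the gaps culling creates), non-normal trait
distributions, genotype-by-block interaction, and trait-dependent culling.
Tests passing on synthetic panels therefore validate the estimators and
plumbing, not the biology of any particular crop.

## Testing conventions and problem sizes

Simulation-based checks run at the design size (46 x 3 x 5). Heritability
recovery (200 replicates per H2 level in {0.2, 0.5, 0.8}) and
genetic-correlation propagation (100 replicates, configured correlation
0.9) are run on the balanced, pre-culling design: the configured truth
H2 = sigma2_g/(sigma2_g + sigma2_e_plot/r) is defined at a fixed plot
size, and culled plots make the plot-mean residual heterogeneous, so the
balanced layout is where the estimator is checked against an unambiguous
truth. Culling is exercised where it matters: the type-I-error simulation
(1000 replicates) runs under the full culled design, and the sensitivity
module's compositionality and tail-probability checks work directly on
culled panels.

## Known limitations

* EMS estimation assumes the two-way layout; with incomplete
  genotype-by-block cells it warns and degrades to the unbalanced ANOVA
  mean squares (REML is the default for exactly this reason).
* The between-within denominator df is approximate under unbalance;
  with ~400 residual df the approximation is inconsequential, but very
  small panels should interpret borderline p-values cautiously.
* Bootstrap Jaccard values at panel sizes near 46 are themselves noisy;
  comparisons should use the reported B and seed, and differences of a few
  hundredths are not meaningful.
* The quadrant split at the 50th percentile with "big" strictly above is a
  convention; panels with many ties near the median can shift counts
  between quadrants and the unassigned group under other tie rules.
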