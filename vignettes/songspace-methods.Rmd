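---
title: "Methods: acoustic spaces, dimorphism metrics, and phylogenetic mixed models"
author: "songspace"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: acoustic spaces, dimorphism metrics, and phylogenetic mixed models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`songspace` implements a comparative-bioacoustics workflow for songbirds in
which both sexes sing — fairy-wrens being the motivating system. The
workflow asks three questions of a multi-population, multi-species song
dataset: how different are male and female songs within each species; how
does song *elaboration* in each sex covary with population-level
life-history traits; and how does male–female song *dimorphism* covary with
those traits — all while controlling for the species' shared ancestry.

This vignette is the package's own account of the methods: the models, the
parameters that matter, the numerical decisions, and what the synthetic
data generator does and does not emulate.

## Data model

The atomic record is the **element**: a single continuous spectrogram
trace, separated from its neighbours by a visible break in time. An element
table has one row per element with identifiers
(`song_id`, `individual_id`, `population`, `species`, `sex`), start/end
times in seconds, and ~22 named acoustic measurements (robust time and
frequency quantiles, bandwidths, entropies, modulation statistics; Hz and
seconds throughout). Validation enforces: `end_time > start_time`, a unique
(individual, population, species, sex) per song, finite features after
imputation, and at least one element per song. Missing values are an error
for every feature except the slope of the peak frequency contour
(`dom_freq_slope`), which is set to 0 — elements too short to fit a slope
show no appreciable modulation, so zero is the faithful value.

Seven **song-level parameters** are derived per song: duration
(max end − min start), element number, element rate (number/duration),
frequency 5% (minimum of the elements' 5% frequencies), frequency 95%
(maximum of the elements' 95% frequencies), frequency range (their
difference — the span between top and bottom frequency among all elements),
and element diversity (below). How the song-level 5%/95% frequencies
aggregate over elements is a genuinely open convention; taking the
min/max is the one reading that makes the range definition exact, so that
is the package's choice (`derive_song_table()`).

Before any forest is grown, highly correlated acoustic variables
(Pearson |r| ≥ 0.95) are pruned greedily in column order — deterministic,
idempotent, zero-variance columns dropped first
(`prune_correlated_features()`). Life-history covariates are screened for
collinearity (|r| > 0.7, pairwise-complete) but only *reported*; exclusion
is an analyst decision (`check_collinearity()`).

## Random-forest acoustic spaces

Supervised forests (`fit_supervised_rf()`) classify songs to sex per
species with the full-scale settings: 10,000 trees, minimal node size 1,
Gini split rule, `mtry` 3 at song level and 5 at element level. Accuracy is
the out-of-bag (OOB) error — each sample predicted only by trees that never
saw it — reported in total and per sex, with mean-decrease-in-Gini variable
importance (permutation importance available behind a flag; impurity is the
default because it matches the Gini split rule).

Unsupervised forests (`fit_unsupervised_rf_proximity()`) use Breiman's
synthetic-contrast construction: a second class is drawn by sampling every
feature independently from its empirical marginal, a two-class forest is
grown, and the proximity of two real samples is the fraction of qualifying
trees in which they share a terminal node, with *qualifying* meaning both
samples out-of-bag (OOB proximity). The implementation delegates to the
\pkg{randomForest} package, which provides exactly this construction; the
contrast scheme and denominator convention are not uniquely pinned down in
the literature that names only the software used, so they are documented
here as the package's convention. Proximities become dissimilarities as
`D = 1 − P`.

Two embeddings turn `D` into coordinates:

* **Classical MDS / principal coordinates** (`classical_mds()`, via
  `stats::cmdscale`): double-centre −D²/2, eigendecompose, scale
  eigenvectors by √eigenvalue. Element-level spaces use five axes, of which
  the first two define the 2-D plane for element diversity. Negative
  eigenvalues are reported but never embedded; with fewer than `k` positive
  eigenvalues the available axes are returned with a warning.
* **Kruskal's non-metric MDS** (`kruskal_nmds()`, via `MASS::isoMDS`):
  stress-1 minimisation with monotone regression, initialised from the
  classical solution with optional jittered restarts, 500 iterations
  maximum, stress tolerance 1e-6, stress reported as a fraction. Duplicate
  points (zero dissimilarities) are nudged to a tiny value below the
  smallest positive dissimilarity, which preserves every rank (primary
  tie treatment); a fully degenerate input is an error. Song-level spaces
  for dimorphism use k = 2.

No attempt is made to reproduce any particular forest implementation
bit-for-bit; forest-derived quantities are validated statistically
(tolerance assertions at 2,000-tree test scale absorb the Monte-Carlo
difference from the 10,000-tree full scale).

## Acoustic areas, element diversity, and dimorphism

The area primitive is the **95% minimum convex polygon** (`mcp()`),
borrowed from home-range estimation: rank points by Euclidean distance from
their arithmetic centroid, keep the nearest `ceiling(0.95 n)` (ties by
input order), and take the convex hull. `ceiling` keeps at least 95% of
points; the convention is stated because reference implementations differ
and none is canonical. Degenerate hulls (fewer than three non-collinear
points) get area 0 and a flag. Areas come from the shoelace formula;
polygon intersections from Sutherland–Hodgman clipping (both polygons are
convex). **Element diversity** of a song is the MCP area of its elements in
the first two element-space axes — songs with scattered, varied elements
occupy more area (`element_diversity_scores()`).

Three **dimorphism metrics** per population
(`dimorphism_metrics()`), computed after z-scoring each embedding axis by
the population's pooled songs (which makes centroid distances comparable
across populations and leaves area *ratios* untouched):

1. `overlap_prop` — area of the intersection of the male and female MCPs as
   a proportion of the population's entire acoustic area;
2. `centroid_distance` — Euclidean distance between the per-sex axis-wise
   mean points, in z-units;
3. `area_size_difference` — |male − female| area over the same denominator
   (dimorphism in song variability).

"Entire acoustic area" is read as the **union** of the two sex polygons,
which guarantees `overlap_prop ∈ [0, 1]`; the alternative reading (MCP of
the pooled points) is available via `denominator = "pooled_mcp"` and
differs only when the union is non-convex. Sample-size asymmetry between
the sexes is removed by **balanced subsampling**
(`balanced_subsample_dimorphism()`): the larger sex is subsampled without
replacement to the size of the smaller, metrics are averaged over 100
iterations, and each iteration draws from a counter-derived child seed so
results are bit-reproducible. When the sexes are balanced every iteration
sees the full data and the per-iteration variance is exactly zero. The
song embedding is computed once and reused across iterations; re-embedding
per iteration would multiply the cost a hundredfold for no inferential
gain.

## Elaboration axes

Five variables are read as "more is more elaborate": song duration, element
number, element rate, frequency range, element diversity. (The raw 5%/95%
frequencies are excluded — a higher or lower pitch is not by itself more
elaborate.) `fit_pca()` standardises them and eigendecomposes the
correlation matrix — eigenvalues sum to 5 by construction — and keeps the
first three components. PCA is fitted on songs pooled across species and
sexes so male and female scores share axes; species and sex enter the
downstream models instead. Eigenvector signs being arbitrary, the dominant
loading of each component is made positive; interpretive labels
("song length", "element rate", "song variability") are left to the
analyst and never asserted by code.

## Bayesian phylogenetic mixed models

`phylo_mmm()` fits the Gaussian mixed model

y = Xβ + Σₖ Zₖuₖ + e,  uₖ ~ N(0, σₖ²Aₖ),  e ~ N(0, σₑ²I)

by a blocked Gibbs sampler (C++ core): (i) (β, u) jointly from their
multivariate-normal full conditional; (ii) each σₖ² from its
scaled-inverse-χ² full conditional; (iii) a scalar working parameter αₖ per
component (non-central parameter expansion, uₖ ≡ αₖũₖ), which de-correlates
small-variance components and improves mixing; (iv) σₑ². Priors follow the
parameter-expanded convention: residual V = 1, ν = 0.002; each random
component V = 1, ν = 1, α.μ = 0, α.V = 25². Fixed effects get a vague
N(0, 10⁸) prior. Chains are deterministic given the seed.

Phylogeny enters as a species-level random effect whose covariance is the
Brownian matrix `C` of the tree (`phylo_vcv()`: shared root-to-ancestor
path lengths). The sex-difference models keep species (and sex × species)
as *fixed* effects as well; the phylogenetic random effect and the species
fixed effects are partially aliased, which the proper prior regularises —
this mirrors the analysis structure the workflow reproduces rather than
inventing a cleaner one, and the configuration is the user's to change.
Whether phylogeny should instead enter *only* through the species random
term is ambiguous in the source analysis; both configurations are
supported (drop `species` from the formula), and the default follows the
stated fixed-effect structure.

Model families and full-scale chains: per-variable sex-difference models
(sex × species fixed; individual and population-in-species random;
1,750,000 / 300 / 15 iterations/burn-in/thinning), elaboration models
(covariate × sex fixed; individual, species, population-in-species random;
300,000 / 300 / 30), dimorphism models (covariate fixed; species and
population-in-species random; 500,000 / 500 / 30). Dimorphism models have
one averaged value per population, so individual ID drops out and the
population term is absorbed alongside the residual — the prior keeps this
proper. The test preset is 20,000 / 2,000 / 10.

Inference summaries: posterior means, 95% quantile credible intervals,
effective sample size by Geyer's initial-positive-sequence estimator
(capped at the stored sample count), lag-1 autocorrelation with a 0.1
flag threshold, and **pMCMC** = min(1, 2·max(0.5/N, min(#>0, #<0)/N)) —
twice the smaller tail mass across zero, floored at half a sample. **DIC**
uses the deviance conditional on the sampled effects (lowest-level focus):
DIC = 2·mean D(θ) − D(θ̄). The marginal-deviance alternative is a known
point of ambiguity; the conditional focus matches the reference ecosystem
for these models. `dredge_by_dic()` ranks all marginality-respecting
subsets of candidate fixed effects under a shared chain spec, after
standardising covariates and setting missing values to 0 (the scaled
mean) so every model sees identical rows; among models within 2 DIC of the
minimum the fewest-parameter model is selected. A guard refuses more than
12 candidate terms unless forced.

## Phylogenetic signal

`blomberg_k()` implements the observed/expected mean-squared-error ratio
for a continuous trait: with the phylogenetic mean â = (1ᵀC⁻¹1)⁻¹1ᵀC⁻¹y,
K = (MSE₀/MSE) standardised by its Brownian expectation
(tr C − n/1ᵀC⁻¹1)/(n−1). K equals 1 exactly on a star tree (an algebraic
identity) and centres on 1 under Brownian evolution; it is invariant to
affine maps of the trait and global rescaling of branch lengths. Tip
values are species means of the song variables, pooling populations — the
tip statistic is another unstated convention; the mean is the default and
the median is available. No randomisation p-value is computed.

## The synthetic-data generator

`simulate_dataset()` emulates the *statistical shape* of the field data,
not its acoustics: 9 species over 15 populations (one species with five
populations, two with two, six with one), individuals nested in
populations with balanced sexes, songs nested in individuals, 4–12
elements per song, 22 features. Species-level trait means evolve by
Brownian motion (rate `bm_sigma2`, default 0.25 on the latent scale —
roughly ±1 SD of species spread across a depth-1 tree, a realistic
between-species spread for log song traits) around fixed roots;
population, individual and song effects are nested Gaussians (SDs 0.2,
0.2, 0.15) and element noise has unit SD. Male elements are shifted by a
per-feature `feature_sex_effect` (default 0.5 SD on three features) and
male songs by `song_sex_effect` on the log-duration and log-element-count
latents (default 0.3), so the derived song duration, element number and
element rate carry the dimorphism. Life-history covariates are drawn
uniformly from field-plausible ranges; `lifehistory_slopes` adds a planted
sex-by-covariate interaction — the male-minus-female gap moves with the
standardised covariate — which is the lever the recovery tests pull.
`simulate_null_dataset()` zeroes every sex effect and slope. All
randomness flows from a single master seed through counter-derived child
seeds (`child_seed()`), so any stage regenerates independently.

What the generator does **not** emulate: real spectro-temporal structure,
correlated feature blocks, measurement error that varies with
signal-to-noise, unbalanced or missing recordings, observer effects, or
type II (male-only) songs. Passing tests therefore demonstrate that the
pipeline recovers structure *of the kind assumed by its models* at field
sample sizes — not that any particular biological dataset satisfies those
assumptions.

## Numerical choices and problem sizes

* MCP retention `ceiling(0.95 n)`; distance ties broken by input order.
* NMDS: zero dissimilarities nudged below the smallest positive value;
  500 iterations; stress tolerance 1e-6.
* Sampler: divergence guard at variance 10¹²; Cholesky failure is an
  error, not a silent retry; all-zero fixed-effect columns (fully imputed
  covariates) are kept with their proper vague prior rather than dropped.
* The test suite runs everything at reduced scale — hundreds of trees,
  thousands of MCMC iterations, datasets of 100–600 songs — with
  statistical tolerances sized to those settings; the full-scale presets
  (10,000 trees; the three chain presets above) are the defaults users
  get. The acceptance script runs the default preset with 500 trees and
  6,000-iteration chains.

## Worked example

```{r example}
library(songspace)
dat <- simulate_dataset(sim_config(seed = 1))
man <- run_manifest(seed = 1, rf_trees = 500, chain = "test")
res <- run_all(dat, man, out_dir = "songspace_out")
res$sex_differences$classification
res$dimorphism$dimorphism
summary(res$elaboration$pca)
res$phylosig
```

## Known limitations

* Gaussian responses only; proportions such as the overlap metric are
  modelled on the identity scale, as in the workflow this package
  reproduces.
* The species fixed-effect / phylogenetic random-effect aliasing means the
  phylogenetic variance component in the sex-difference family is not
  separately interpretable; it acts as a control, not an estimand.
* With one value per population, the dimorphism models cannot separate
  population variance from residual variance; credible intervals on those
  components are prior-dominated.
* K at 9 species is a noisy estimator; the package reports it without a
  significance test.
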