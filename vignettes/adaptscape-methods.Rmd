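---
title: "Methods: climate-adaptive variation in range forecasts and evolutionary rescue"
author: "adaptscape"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: climate-adaptive variation in range forecasts}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Overview

Species distribution forecasts usually treat a species as a single
climatic unit. When populations are locally adapted — some tolerating
hot, dry summers, others bound to cool, wet conditions — that
simplification can overstate projected range losses and hide where gene
flow from pre-adapted populations ("evolutionary rescue") could keep
declining populations in place. `adaptscape` implements the full
analytical chain for incorporating climate-adaptive genetic variation
into such assessments:

1. **GEA** — detect climate-adaptive SNPs by two independent
   genotype–environment association methods and keep only their
   intersection;
2. **classification** — place individuals in a constrained ordination of
   their adaptive genotypes and label them hot–dry, cold–wet or
   intermediate, then roll labels up to populations;
3. **ENM** — fit and project ensemble niche models separately for the
   full species and for each adaptive group, and compare projected range
   change, range overlap and niche overlap;
4. **connectivity** — build resistance surfaces, compute circuit-theory
   resistance distances and current density, regress genetic
   differentiation on resistance, and map gene-flow potential from
   hot–dry to cold–wet locations.

A synthetic-data generator produces landscapes, genotypes, occurrence
records and genetic distances with the statistical structure the
analysis assumes, so every stage is testable end-to-end without any
external download.

# The synthetic study system

The generator emulates a ddRAD-style landscape-genomics study of a
cave-roosting forest bat:

* **Landscape** (`generate_climate_rasters`): each climate layer is a
  unit-SD linear gradient plus a Gaussian random field (white noise
  smoothed with a kernel of SD `autocorrelation_range` cells, the
  simplest generator with controllable spatial autocorrelation — a full
  geostatistical simulator would add nothing the tests need). Layers are
  standardized; successive layers rotate the gradient by 90° so a
  temperature-like (`bio1`) and rainfall-like (`bio2`) axis are
  decorrelated by construction. Futures are deterministic per-layer
  shifts; several shift sets stand in for general circulation models.
* **Genotypes** (`simulate_genotypes`): neutral loci follow a
  Balding–Nichols island model (ancestral frequency Uniform(0.05, 0.95),
  population frequencies Beta-distributed with variance
  p(1−p)·F~ST~), chosen over a coalescent because its
  expected Weir–Cockerham θ is known and fast to verify. Adaptive loci
  apply a logistic shift of `adaptive_slope` log-odds per SD of climate
  *on top of the population frequency*, so selection is layered on
  drift and a slope of zero reduces exactly to the neutral model — the
  property the generator's own indistinguishability test checks. Loci
  are unlinked and additive, as the downstream per-SNP tests assume.
* **Defaults** mirror the scale of the real datasets the framework was
  built for: 15 roosts × 20 individuals (n = 300), 2000 neutral + 20
  adaptive loci, F~ST~ 0.1, slope 2. Roosts are placed at random cells,
  so all members of a roost share its climate, as cave-roost sampling
  implies.
* **Occurrences** (`simulate_occurrences`): cells are drawn with
  probability proportional to a logistic suitability function of the
  layers. In the pipeline the two adaptive groups share a rainfall
  preference (+2.5 logit/SD) and diverge in temperature (±2), with
  intercept −3 — a restricted, mesic niche occupying roughly a third of
  the landscape, as for the real forest specialists. The hot–dry group
  is the scarcer record class (60 vs 120 points), reflecting the real
  surveys where hot-adapted records were the smallest class; this
  asymmetry is what makes the pooled model representative of the cool
  core of the range.
* **IBR distances** (`simulate_ibr_distances`): linearized genetic
  distances are β × resistance distance plus symmetric Gaussian noise,
  clipped at zero — the structure the landscape-genetics stage assumes.

What the generator does **not** emulate: linkage disequilibrium, range
expansion history, isolation by environment confounded with isolation by
distance, spatially biased sampling, and observation error in occurrence
records. Passing tests therefore demonstrate the correctness and
calibration of the methods under their own assumptions, not robustness
to every pathology of real data.

# Genotype–environment association

`fit_rda` implements constrained ordination from first principles: the
centered genotype matrix is projected onto the standardized climate
predictors and the fitted matrix decomposed by SVD. Genotypes are
centered but *not* scaled by default, keeping loadings comparable
across loci of similar frequency (scaling is available as an option).
Candidates (`rda_outliers`) are loci whose loading on any retained axis
lies more than 3 SD from the axis mean — the conventional threshold in
RDA-based outlier scans, configurable because no universal value
exists.

`fit_latent_association` is a transparent latent-factor model: the
first K principal components of the genotype matrix (after regressing
out climate) enter a per-locus linear model alongside each climate
variable. Z-scores are calibrated by genomic control
(λ = median(z²)/0.4549) and converted to q-values by Benjamini–Hochberg
within each variable. Because the factors are estimated from the same
data, λ runs slightly above 1 (typically 1.05–1.3 at the default
conditions; with the true population labels it is ≈1.0); the
calibration absorbs this, and the observed false-positive rate stays at
or below the nominal q. `select_K` picks the largest consecutive
eigenvalue drop ratio of the scree, returning 0 when no ratio exceeds
1.3 — for k populations the drop sits at k − 1, so `k_max` must be at
least the plausible number of demes (the pipeline default is 20).

Each method's candidates are unioned across the two climate variables
first, and only loci flagged by **both** methods are retained
(`intersect_candidates`); multiple-testing control is per variable, the
union being part of the conservative intersection design. At the
default conditions the intersection recovers ≈94% of truly adaptive
loci with a false-discovery proportion ≈0.04, below either method
alone.

# Classifying adaptive groups

`score_individuals` refits the ordination on the candidate loci only
and takes each individual's site score on the constrained axis with the
largest absolute temperature biplot score, oriented so the temperature
vector points positive (hot–dry). One axis is used because the
candidate set is driven by two (correlated) climate axes and the
temperature-anchored axis captures the hot–cold contrast the grouping
needs. The intermediate band is ±0.25 SD of the score distribution by
default — narrow enough that symmetric trimodal data yield three
groups, and explicitly configurable since no principled universal value
exists. Populations are labelled by a 0.6 majority among their
*non-intermediate* members ("primarily adapted"), with populations of
fewer than three individuals flagged low-confidence.

# Ensemble niche models

The ensemble uses three transparent member algorithms — a percentile
climate envelope, a quadratic logistic regression, and an L1-penalized
logistic model on linear, quadratic and product features (a regularized
exponential-family model in the spirit of Maxent) — rather than an
opaque committee; each member is specified exactly and has closed-form
landmark behaviour used in tests. Members are cross-validated on random
70/30 presence/background splits, 10 replicates (5 when presences
number fewer than 50). Members with held-out TSS ≥ 0.4 enter the
ensemble with TSS-proportional weights; the ensemble's suitability is
the weighted member mean, affinely rescaled to [0, 1] on the pooled
held-out data, and binarized at its TSS-maximizing threshold (101
evenly spaced thresholds). That present-day threshold is reused for
futures, as range change requires one consistent rule. Projections onto
several pseudo-GCM stacks are merged by the unweighted per-cell mean
before binarization.

Predictors are clamped to their training range before the polynomial
feature expansion when predicting (Maxent-style clamping); without it,
quadratic members extrapolate upward outside the calibration range and
future projections become dominated by out-of-range artefacts.

Background is a uniform sample of valid non-presence cells (default
10,000 or all free cells); presences are snapped to cell centres and
deduplicated per cell. Niche overlap is Schoener's
D = 1 − ½Σ|p₁ − p₂| on suitability surfaces normalized over the shared
geography (an environment-space variant on a binned grid would need an
occurrence-density estimator that is out of scope here), with a
label-permutation identity test for "lower overlap than random". Null
models compare the observed AUC with models fitted to random presence
sets of the same size.

# Circuit-theory connectivity

Landscape layers become resistance surfaces through breakpoint tables
with costs in [1, 100] (1 = no resistance, 100 = strong barrier),
piecewise-constant or linearly interpolated. Surfaces combine by
cellwise mean by default (sum and product variants rescale back to
[1, 100]). The raster graph connects 8-neighbours with conductance
equal to the mean of the two cells' conductances, diagonals divided by
√2 — the Circuitscape convention, with a 4-neighbour option since the
original setting is rarely reported. Effective resistance solves the
grounded sparse Laplacian (one Cholesky factorization per connected
component, one solve per focal node); current density accumulates
½Σ|incident branch currents| per cell over all source–target pairs with
equal weight. Pairs in different components are reported as infinite
with a warning rather than an error.

Isolation-by-resistance support is measured by the Mantel correlation
(Pearson, simultaneous row/column permutations) plus an ordinary
least-squares R² over the off-diagonal pairs, with candidate surfaces
ranked by R². A mixed-model (MLPE) regression would be a natural
extension but the simple pair-level R² is what the ranking needs.
`rescue_potential` then takes the top-ranked surface and maps current
density from all hot–dry locations (sources) to all cold–wet locations
(targets), summarizing each target by its mean effective resistance
from the sources — low values mark places evolutionary rescue could
plausibly reach.

# Numerical and design notes

* All generators take explicit seeds and are bit-reproducible; seeded
  code restores the caller's RNG state.
* Genepop I/O: 2- and 3-digit codes, `00`/`000` alleles = missing,
  biallelic loci recoded to minor-allele counts (ties counted on the
  higher-coded allele so write→read round-trips), >2-allele loci
  dropped with a warning. Missing genotypes are imputed with the
  per-locus modal genotype (ties toward the lower count), the standard
  completion for ordination-based scans.
* Multilocus θ is the ratio of summed variance components (ratio of
  averages), stable for RAD-scale data; negative estimates are reported
  as computed, and linearization θ/(1−θ) clamps the denominator at
  10⁻⁶.
* TSS threshold searches are exhaustive over a fixed grid, making
  binarization deterministic; AUC is the rank statistic, invariant to
  monotone transforms.
* Degenerate inputs fail loudly: zero-variance standardization,
  collinear predictors (named), empty candidate sets (with advice to
  relax thresholds), all-zero suitability, empty population blocks,
  over-large background requests.

# Problem sizes

The test suite and the acceptance script run the whole pipeline on a
48 × 48 landscape, 300 individuals × 2020 loci, 60–180 occurrence
records, 2000 background points and 15 focal roosts — sizes chosen so a
full run takes seconds while every statistical property (θ recovery,
GEA power/FDP, calibration, the range-loss comparison, Mantel type-I
error) is measurable with stable margins. Statistical acceptance checks
average 20 fixed-seed replicates.

# Known limitations

* The latent-factor scan is a PCA-adjusted regression with genomic
  control — a transparent approximation to richer latent-factor mixed
  models; its λ is mildly inflated and relies on the calibration step.
* Niche overlap is computed in geographic space; ecospat-style
  environment-space density overlap is not implemented.
* No linkage, no temporal selection dynamics, no demographic inference;
  the generator's truth labels are per-SNP and marginal.
* Projection uses a fixed study extent; dispersal-limited projection
  beyond extent clipping is out of scope.
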