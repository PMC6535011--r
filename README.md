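# adaptscape

Incorporating climate-adaptive genetic variation into climate-change
vulnerability assessment.

Forecasts of species range loss usually treat a species as one climatic
unit. When populations are locally adapted — some tolerating hot, dry
summers, others tied to cool, wet conditions — a single pooled model can
overstate future losses and hide where gene flow from already-adapted
populations could rescue declining ones. `adaptscape` implements the
whole analytical chain for testing that, aimed at landscape genomicists
and spatial ecologists working with SNP panels, occurrence records and
climate rasters:

* **Genotype–environment association (GEA).** Candidate
  climate-adaptive SNPs are loci flagged by *both* of two methods:
  (1) constrained ordination (RDA) of the centered genotype matrix
  *Y* on standardized climate predictors *X* — SVD of
  *Ŷ = X(XᵀX)⁻¹XᵀY*, with outliers beyond 3 SD of the axis loading
  distribution — and (2) a latent-factor association scan: per-locus
  regression of genotype on climate plus *K* principal-component
  factors, z-scores calibrated by genomic control
  (λ = median(z²)/0.4549) and Benjamini–Hochberg q-values.
* **Adaptive-group classification.** Individuals are scored on the
  temperature-anchored constrained axis of an RDA restricted to the
  candidate SNPs and labelled hot–dry / cold–wet / intermediate;
  populations are labelled by majority of their non-intermediate
  members.
* **Ensemble niche models (ENM).** Three member algorithms (percentile
  envelope, quadratic logistic, L1-regularized Maxent-like model) are
  cross-validated (rank AUC; TSS = sensitivity + specificity − 1
  maximized over thresholds), combined with TSS-proportional weights,
  binarized at the ensemble's TSS-optimal threshold, and projected onto
  pseudo-GCM future climates — separately for the full species and for
  each adaptive group. Reports percent suitable area, percent range
  change, union of adaptive ranges, range overlap, and Schoener's
  D = 1 − ½Σ|p₁ − p₂| with a permutation identity test.
* **Circuit-theory connectivity.** Resistance surfaces (costs 1–100),
  effective resistance between focal sites from sparse graph-Laplacian
  solves, current-density maps, Mantel + R² isolation-by-resistance
  regression of linearized F~ST~ (θ/(1−θ), Weir & Cockerham), and
  evolutionary-rescue maps of gene-flow potential from hot–dry to
  cold–wet locations.
* **Synthetic data.** Every input has a seeded generator (structured
  genotypes with known adaptive loci, autocorrelated climate rasters,
  occurrences from a known suitability surface, genetic distances with
  a known isolation-by-resistance slope), so the full pipeline runs and
  is tested without any download. Genepop and ESRI ASCII grid I/O are
  included for real data.

## Worked example

The bundled pipeline runs the whole framework on a synthetic study
system (48 × 48 landscape, 15 roosts × 20 individuals, 2000 neutral +
20 adaptive loci, hot–dry-biased warming scenarios):

```r
library(adaptscape)
res <- run_pipeline(pipeline_config(seed = 1))
```

```
[  0.1s] gea: K = 14 latent factors
[  0.4s] gea: 24 RDA + 20 latent -> 18 intersection candidates
[  0.4s] classify: cold_wet 146, hot_dry 114, intermediate 40
[  1.7s] enm[all]: AUC 0.786 TSS 0.437, 39.3% -> 17.2% suitable
[  1.9s] enm[hot_dry]: AUC 0.843 TSS 0.576, 28.7% -> 44.1% suitable
[  2.2s] enm[cold_wet]: AUC 0.844 TSS 0.573, 35.8% -> 0.3% suitable
[  2.6s] connect: best surface 'forest_slope' (R2 = 0.997)
[  3.0s] rescue: 6 hot_dry -> 8 cold_wet locations
```

The per-group evaluation table (`res$summary$table1`):

```
    group   n   AUC   TSS pct_present pct_future pct_change
      all 172 0.786 0.437       39.32      17.23     -56.18
  hot_dry  58 0.843 0.576       28.69      44.10      53.71
 cold_wet 115 0.844 0.573       35.81       0.35     -99.03
```

Read it like a niche-modelling results table: `n` is the number of
occupied cells used, AUC/TSS the pooled held-out ensemble evaluation,
and the last three columns the percentage of the landscape suitable now
and in 2070-style shifted climate, and the relative range change. The
pooled ("all") model projects a 56% range loss. Modelling the two
adaptive groups separately, the hot–dry group *gains* (+54%) while the
cold–wet group collapses (−99%); the union of their ranges loses only
19%:

```
combined adaptive range change: -18.78%
projected loss reduction: 66.6%
Schoener D between groups: 0.744
best IBR surface: forest_slope (R2 = 0.997)
mean source->target resistance: 29.4
```

So accounting for intraspecific adaptation cuts the projected loss by
two-thirds here — the qualitative behaviour this framework was built to
measure. The connectivity stage confirms the generating resistance
surface (forest + slope) as the best isolation-by-resistance predictor
and summarizes the cost of gene flow from hot–dry roosts to each
cold–wet roost (`res$rescue$target_summary`); low mean resistance marks
populations that rescue could plausibly reach.

Individual stages are available as plain functions (`read_genepop()`,
`filter_loci()`, `impute_missing()`, `pairwise_fst()`, `fit_rda()`,
`rda_outliers()`, `fit_latent_association()`, `intersect_candidates()`,
`score_individuals()`, `fit_enm()`, `project_ensemble()`,
`range_change()`, `schoener_d()`, `build_graph()`,
`effective_resistance()`, `current_density()`, `ibr_regression()`,
`rescue_potential()`, …) and accept your own rasters (ESRI ASCII),
Genepop files and occurrence CSVs. See the methods vignette
(`vignettes/adaptscape-methods.Rmd`) for the models, defaults and their
rationale.

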