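---
title: "Ensemble range modelling with rangecast: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ensemble range modelling with rangecast}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

`rangecast` implements a complete presence-only ensemble species
distribution modelling (SDM) workflow of the kind used to hindcast and
forecast the range of wide-ranging vertebrates from opportunistic sighting
archives: record cleaning and spatial thinning, observer-bias-aware
pseudo-absence generation, collinearity screening, a multi-algorithm
suitability roster with threshold-gated TSS-weighted ensembling,
dispersal-bounded range-change estimation, and MESS extrapolation
diagnostics. This vignette documents the statistical model behind each
stage, the tunable parameters with their defaults and units, and the design
decisions taken where the methodology left genuine freedom.

## The modelling problem

The data are presence-only point records of a mobile, easily recognised
species, collected opportunistically, together with co-registered
continuous environmental raster layers (bioclim-style variables such as
`bio13`, precipitation of the wettest month, or `bio15`, precipitation
seasonality). The goal is a habitat-suitability surface
$\hat p(\mathbf{x})$ over the landscape, a binary range map derived from
it, and the percentage change of that range when the climate layers are
replaced by a past or future scenario.

Two well-known pathologies of opportunistic archives drive the design:

* **Observation bias.** Sightings concentrate where observers go (roads,
  towns), not only where the species lives. Pseudo-absences drawn uniformly
  would therefore teach the model the observation process rather than the
  niche. `rangecast` estimates a sampling-effort surface from sightings of
  *analogue species* (taxa with similar detectability that share the
  observation process but not the niche) and draws pseudo-absences with
  probability proportional to that effort.
* **Environmental complementarity.** Pseudo-absences should represent
  environments *unlike* presences. A product-Gaussian kernel density is
  fitted to the presence records in the principal-component space of the
  standardised predictors; candidate cells are weighted by the complement
  `1 - d/max(d)` of that density before the effort weighting is applied.

## Stage-by-stage model description

### Cleaning and thinning

`clean()` drops records with reported coordinate uncertainty above 5 km,
records before 1970 or without a year, fossil and absence records, exact
coordinate duplicates (after rounding to 6 decimals), records within 10 km
of supplied city centres, records inside user polygons, and spatial
outliers whose nearest neighbour lies beyond 30 km. Records with *missing*
uncertainty are kept by default (observer-estimated distances are
admissible); a strict flag reverses this. The outlier rule is iterated to a
fixed point inside `clean()` so that cleaning is idempotent
(`clean(clean(x)) = clean(x)`); the exported primitive `remove_outliers()`
is the corresponding single pass. `thin()` enforces a minimum 30-km
pairwise spacing by a seeded random ordering followed by greedy
accept-if-far-enough — the simplest reproducible scheme; it makes no
attempt to maximise the retained count. Distances are Euclidean on planar
kilometre grids and great-circle (haversine, spherical radius 6371.0088 km)
for longitude/latitude data.

### Pseudo-absences

`sample_pseudoabsences()` draws exactly one pseudo-absence per presence
(1:1 ratio) with cell weight

$$w(c) \propto \Big(1 - \frac{d(c)}{\max_c d(c)}\Big)\, b(c),$$

where $d$ is the presence kernel density evaluated at the cell and $b$ the
effort surface rescaled to a maximum of one. Candidates closer than 30 km
to any presence or accepted pseudo-absence are rejected; after $50n$
rejections the requested count is declared infeasible and reported. Open
choices fixed here: the complement transform is the simplest monotone map
bounded in $[0,1]$; kernel and effort weights combine multiplicatively; the
number of retained components defaults to the smallest count explaining
95% of predictor variance; per-component bandwidths follow Scott's rule;
the spacing constraint is enforced *during* sampling (thinning afterwards
would distort the intended weighting); and the kernel is fitted on
presences only.

### Predictor selection and standardisation

`vif_stepwise()` repeatedly removes the predictor with the highest variance
inflation factor ($\mathrm{VIF}_j = 1/(1-R^2_j)$ from regressing predictor
$j$ on the others) until all remaining VIFs are at or below 10. Ties break
by column order. The VIF is computed on the combined presence +
pseudo-absence table. `scale_centre()` standardises each retained column to
mean 0 / sd 1 and stores the parameters; scenario stacks are always
transformed with these *fitting-era* parameters, never re-standardised,
because projections must live in the fitted model's coordinate system.

### The algorithm roster

`fit_all()` fits nine learners on each of six independent random 70/30
splits (54 candidate models) and scores each on its own 30% holdout:

| id | learner | backing |
|----|---------|---------|
| `bioclim` | percentile climate envelope | in-house (see below) |
| `glm` | logistic regression, linear + quadratic terms | `stats::glm` |
| `gam` | smooth additive logistic model | `mgcv` |
| `cta` | classification tree | `rpart` |
| `rf` | random forest (300 trees) | `randomForest` |
| `gbm` | gradient-boosted trees (150 rounds, depth 3, learning rate 0.1) | `xgboost` |
| `ann` | one-hidden-layer neural net (5 units, weight decay 5e-3) | `nnet` |
| `fda` | linear discriminant analysis, posterior probability | `MASS` |
| `mars` | adaptive regression splines | in-house |

A tenth slot accepts any user learner via `register_algorithm()`; a
maximum-entropy learner is deliberately not bundled (its feature and
regularisation machinery is a project of its own). The `bioclim` envelope
scores a site per variable by $2\min(p, 1-p)$, where $p$ is the empirical
fraction of presence values at or below the site's value (0 outside the
presence min–max), and takes the minimum over variables, so the score is 1
only at the per-variable medians. The in-house `mars` learner selects
reflected hinge pairs $\max(0, x - t), \max(0, t - x)$ greedily by
least-squares screening over decile knots (up to 8 pairs, relative RSS
improvement threshold $10^{-4}$) and then fits a binomial GLM on the
selected basis. Discriminant analysis is linear (`MASS::lda`) rather than a
flexible variant, for the same dependency reason as the spline learner —
both slots keep the roster's diversity of inductive biases. The splits and
every stochastic learner are seeded deterministically from
`(seed, repeat, algorithm)`, so repeats differ in both the split and the
learner's own randomness.

### Evaluation and gating

Each model's holdout predictions yield AUC (rank-based Mann–Whitney
estimate, ties one half), the threshold maximising TSS (swept over the
unique observed scores, smallest optimum on ties, `>=` convention), and
sensitivity/specificity/TSS/Kappa at that threshold. Models enter the
ensemble iff TSS ≥ 0.7, AUC ≥ 0.9 and Kappa ≥ 0.7 (inclusive); failed fits
are excluded with their error recorded. Member weights are proportional to
TSS. Ensemble calibration is additionally summarised by the continuous
Boyce index: 101 overlapping windows of width one tenth of the observed
suitability range, Spearman correlation of the presence-to-expected
frequency ratio against window midpoint, windows with zero expected
frequency skipped. With these window defaults roughly ten windows are
effectively independent, so the index's null standard deviation is about
one third — single-run Boyce values should be read with that granularity in
mind. The index is computed on the full fitting table, and labelled as
such, since the holdout geography is not retained per member.

### Projection, range change, novelty

`ensemble_predict()` standardises a scenario stack with the fitting-era
parameters and returns the TSS-weighted member mean per cell. Binarisation
uses the threshold that maximises TSS on the ensemble's own fitting-table
predictions (recorded in the report). Range change compares occupied cell
counts — the synthetic grids are planar and equal-area, so counts are
areas — under two dispersal assumptions: unlimited (whole projected range
counts) and none (only the overlap with the current range counts).
`mess_map()` computes the multivariate environmental similarity of every
cell to the fitting points per variable (piecewise-linear percentile
similarity, strict less-than convention for ties) and aggregates by
cell-wise minimum; negative values flag novel climate where projections are
extrapolations. `correlation_shift()` reports the change in the predictors'
Pearson correlation matrix between two stacks. Note that the synthetic
scenario generator applies cell-wise linear transforms, which cannot change
Pearson correlations; on synthetic scenarios this diagnostic is therefore
an identical-zero control, and its numerics are validated on hand-written
stacks instead.

## The synthetic landscape and what passing tests mean

Because the real occurrence archives and climate grids behind such studies
are large external downloads, every stage is exercised on synthetic
landscapes with known ground truth. `generate_predictor_stack()` realises
each predictor as Gaussian white noise convolved with a Gaussian kernel of
the requested autocorrelation length (reflection padding, then
standardised), on a planar equal-area grid. The generating niche is
logistic: $p = \mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j x_j + \sum_j
\gamma_j x_j^2)$. Occurrences are drawn per cell with probability
proportional to suitability × effort and jittered uniformly within the
cell; 10% of records deliberately violate cleaning rules (split among
excess uncertainty, missing or pre-1970 years, fossil/absence flags, and
far outliers). Analogue sightings are drawn from the effort surface alone.
Scenario stacks apply per-layer cell-wise transforms `factor * x + delta`.

The default study conditions were calibrated once, jointly, to make the
generator realise the behaviour the workflow is designed for, and then
frozen: a 200 × 200 grid of 5-km cells (a 1000-km domain, point density
comparable to a regional atlas compilation); five predictors with 100-km
autocorrelation; niche intercept −1 with coefficients +4 (`bio13`), −3
(`bio15`), +2 (`bio18`) and a quadratic optimum −1.5 on `bio13` (two
nuisance layers carry no signal); an effort surface `exp(1.5 z)` of a
150-km autocorrelated field, rescaled to max 1; 500 presences and 2000
analogue sightings. Under these conditions the cleaned, thinned fitting
sets hold roughly 60–130 presences, the 54-model roster reaches median
holdout TSS above 0.7, the gated ensemble recovers the true suitability
ranking with Spearman ρ ≈ 0.85–0.95 on 10,000 cells unseen in fitting, and
the unlimited-dispersal range-change estimate tracks the true change of
the 0.5-level range to within about 5–15 percentage points — the
scenario-projection step is the least precise stage, because binarising an
uncalibrated consensus surface at its own max-TSS threshold responds more
smoothly to climate shifts than the sharp true niche does.

What the synthetic landscape does *not* emulate: real spatial structure
(coasts, mountain ranges, monsoon gradients), non-stationary observation
effort, temporal drift in climate normals, species interactions, and
dispersal dynamics. Passing tests therefore demonstrate that the machinery
is implemented correctly and recovers a known data-generating process
through the full bias-correction chain — not that any particular real-world
inference is right.

## Numerical conventions and degenerate inputs

* Thresholding uses `>=` everywhere (a score equal to the threshold
  predicts presence); threshold candidates are the observed unique scores,
  never a fixed grid.
* Max-TSS ties resolve to the smallest optimal candidate; max-VIF ties to
  the earliest column.
* Learner outputs are clipped to `[0, 1]`; constant-output models get
  permutation importance 0 on every variable and are flagged.
* Constant predictor columns are an error for standardisation, VIF, the
  environmental kernel, and MESS (a constant reference has no percentile
  scale).
* Nodata propagates as `NA` (never 0); points on nodata cells are dropped
  and counted at extraction.
* Grids are cell-centre registered with row 1 as the northernmost row;
  rasters round-trip through plain-text ESRI ASCII grids with a JSON
  sidecar for names, cell size and seed.
* One global seed drives everything; each stage derives its own 32-bit seed
  as `(48271 * seed + 16807 * hash(stage)) mod (2^31 - 19) + 1`, so any
  stage can be re-run in isolation.

## Known limitations

The greedy thinning does not maximise the retained sample; the
pseudo-absence rejection sampler can declare small/tightly-spaced problems
infeasible (it reports the achievable count); the Boyce index is computed
on the fitting table rather than held-out geography; range change is
counted in cells and assumes equal-area grids; and the scenario generator's
linear shifts cannot produce novel correlation structure, so
`correlation_shift()` only becomes informative with externally supplied
scenario stacks.
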