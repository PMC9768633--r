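---
title: "Building regional deprivation indices: model, harmonization and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building regional deprivation indices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deprindex)
```

## The problem

Health data aggregated to administrative regions (deaths, cancer
registrations, claims) usually carry no information on the socioeconomic
position of the individuals behind the counts. A regional deprivation
index summarizes the socioeconomic situation of each region's resident
population in a single score, so that health outcomes can be analysed
along a socioeconomic gradient at the area level. This package
implements the construction used by the German Index of Socioeconomic
Deprivation: three subdimensions — education, employment, income —
measured by three administrative indicators each, combined by
principal-component weighting into a score in [0, 1] per region and
year, on each level of the administrative hierarchy.

An important caveat is inherited from the design itself: the index
describes *regions*, not people. Associations between area deprivation
and area health outcomes must not be read as individual-level causation
(the ecological fallacy).

## The model

### Weighting by pooled principal components

For each subdimension the three harmonized indicators are z-standardized
over the pooled region × year observations and the first eigenvector of
their correlation matrix is extracted. Writing $\lambda_i$ for the
loading of indicator $i$ (its correlation with the first component) and
$\eta = \sum_i \lambda_i^2$ for the first eigenvalue, the
within-dimension weight share is $s_i = 100\,\lambda_i^2/\sum_j
\lambda_j^2$ and the total-index share $g_i = s_i/3$. A first component
explaining less than 50% of the dimension variance (a tunable threshold)
triggers a warning, since the one-dimensionality of the subdimension is
then questionable; the second and third eigenvalues are reported as
diagnostics.

Two pooling choices deserve comment:

* **Pooling window.** The default pool is 2001–2019. The early years
  1998–2000 are the most heavily imputed part of the panel, and weights
  estimated from imputed values would partly reflect the imputation
  model rather than the data. Scores *are* produced for 1998–2000 — the
  standardization constants (pooled means and SDs) are frozen from the
  fit and reused, so early years are scored on the same scale.
* **Global pooling, not per-year.** Standardizing per year before
  pooling would erase between-year variation, which carries real
  information about how regions move; the pooled correlations
  deliberately use it. This is a genuine design fork; the package takes
  the global-pooling branch and exposes `pool_years` for sensitivity
  analyses.

The component's sign is oriented so that deprivation-increasing
indicators (per the polarity declared in the indicator specs) load
positively; the orientation is a property test, not a convention left to
the eigen-solver.

### Scoring, normalization, composition

Subdimension scores are regression-method component scores
$\mathrm{score} = \sum_i (\lambda_i/\eta)\, z_i$. Any affine-equivalent
scoring convention would give the identical final index, because scores
are immediately min-max normalized to [0, 1] within each year; this
invariance is asserted by a test rather than assumed. The three
normalized sub-scores are added — each subdimension weighs one third —
and the sum is renormalized per year.

### Aggregation and quintiles

Scores are built at the municipality level (each municipality carries
the finest available value of every indicator: its GVB's value for
GVB-native indicators, its district's for district-native ones) and
aggregated upward by population-weighted means with yearly population
weights, then renormalized within each level and year, so the index
spans exactly [0, 1] on every level. Weighted means are associative:
aggregating municipality → district directly equals municipality → GVB →
district, provided renormalization happens only at the final level; the
package's `aggregate_scores()` therefore exposes `renormalize` and the
pipeline always aggregates directly from the municipality grain.

Quintiles are computed over *units*, not population: regions are ranked
within each level-year and split by
$q = \lfloor (r-1) \cdot 5/n \rfloor + 1$ with minimum ranks for ties,
so tied regions share the lower quintile and sizes differ by at most one
unit (401 distinct values split 81/80/80/80/80). Population-weighted
fifths would be a defensible alternative reading of "five groups of
twenty percent"; unit-based fifths match a distribution-of-index-values
reading and are deterministic. The three-group collapse used by the epi
functions maps quintile 1 → `low`, 2–4 → `mid`, 5 → `high`.

The GVB-level index is emitted with an uncertainty flag: only three of
the nine indicators vary below the district level, so sub-district
contrasts rest on a third of the index's information.

## Harmonization

The harmonization steps run in a fixed order — broadcast, deflation/log,
break correction, school-reform correction, East–West correction, gap
carry-forward, model imputation — chosen so that artefact removal
precedes imputation and the imputation model never learns artefacts.
Every step appends to a per-panel correction ledger; re-applying a
correction to the same indicator is refused, and the ledger (with
parameters and row counts) can be written as a sidecar CSV.

* **Deflation and log.** Currency indicators (tax revenue, gross wage,
  household income) are divided by a per-year price index and
  log-transformed. The price index is a user input with a declared base
  year; the identity default warns, because the final scores are
  invariant to any year-constant rescaling but real purchasing-power
  adjustment needs a real index. Non-positive values are a hard error.
* **Reporting break.** The level shift at a known changeover year is the
  step coefficient of `value ~ region + year + post`, i.e. the jump net
  of region levels and secular trend; pre-break values are shifted onto
  the post-break level. On noiseless fixtures the recovery is exact; on
  strongly autocorrelated panels the estimate is noisy (the step and the
  trend are nearly collinear over a short window), which is tolerable
  here because a uniform level shift is absorbed by the yearly
  normalization anyway.
* **School-reform correction.** The affected (state, year) cells are
  configuration input, not auto-detected — the reform calendar is
  jurisdiction knowledge that should not be hard-coded. The cell effect
  comes from `value ~ region + year + reform_dummy` and is subtracted in
  affected cells only.
* **East–West correction.** The mean West–East difference, estimated on
  the pooled pre-correction panel at the region level (pooled across
  years; a per-year Δ would confound the correction with trend noise),
  is added to all East regions. The East state set is configurable; for
  the German geography the natural default is the five East states with
  Berlin counted as West, Berlin's mixed history making it genuinely
  ambiguous. The model records a bimodality diagnostic before and after:
  the package uses a kernel-density mode count (local maxima above 10%
  of the peak, separated by a valley deeper than 10% of the lower peak)
  as its bimodality flag, and checks afterwards that the corrected
  indicator's correlations with the other education indicators carry the
  polarity-expected signs.
* **Gap carry-forward.** A one-year reporting gap is filled by copying
  the donor year per region; both years are explicit parameters. Cells
  are flagged as imputed; regions missing the donor year fall through to
  model imputation.
* **Random-intercept imputation.** Missing years (the start of the
  panel for late-starting indicators) are predicted from
  `value ~ year + (1 | region)` fitted with lme4. Observed cells are
  never overwritten. In the noiseless limit the prediction is exact; on
  simulated panels with known truth the mean absolute error stays well
  inside three times the noise SD.

After harmonization, every indicator is complete at its native level
for the full panel window — the pipeline errors rather than silently
scoring an incomplete panel.

## The synthetic-data generator

The generator exists so that every operation above is testable without
external data. It emulates the structure of the German setting, not its
values:

* a nested hierarchy with log-normal municipality populations (default
  scaled shape 500/200/50/12/5 across the five levels in 5 states, two
  of them "East"; the real level counts 10,799/4,411/401/96/38 sit
  behind `full_scale = TRUE`);
* three correlated latent deprivation factors per district and year
  (unit variance; cross-correlations defaulting to 0.52/0.66/0.69, the
  observed subdimension-score correlations; an AR(1) temporal part with
  ρ = 0.9 over a region-constant base, so the panel has the betweeen-year
  variation the pooled PCA uses), with GVB-level factors mixing the
  district factor with local noise;
* indicators as noisy affine images of the factors. The generating
  coefficients are *solved for* (`solve_generating_loadings()`) so that
  the implied correlation matrix has exactly the published loading
  pattern as its first-component loadings — feeding the target loadings
  in directly as factor-model coefficients would not reproduce them,
  because PC loadings of a rank-one-plus-diagonal correlation matrix are
  flatter than the generating coefficients;
* the documented pathologies: availability windows per indicator, a
  reporting-break shift on the two employee-qualification indicators, a
  gap year (2012, carried forward from 2011 — the availability calendar
  identifies 2012, not 2013, as the gap), reform dips in configured
  state-years, an East offset on the employees-without-qualification
  indicator scaled to produce a clearly bimodal raw distribution
  (offset 6 percentage points against a cross-district SD of 1.5), and
  district-only resolution of the unemployment and employment rates in
  1998–2000.

Determinism is a contract: all generation runs under a locally seeded
RNG whose state is restored afterwards, so the same seed reproduces the
same data on any platform and generation never disturbs the caller's
RNG stream.

For parameter-recovery experiments a stripped design
(`recovery_config()`) removes persistence, artefacts and the calendar
and flattens the hierarchy, giving i.i.d. pooled observations — 263
regions over 19 years ≈ 5,000 observations — under which the pooled PCA
recovers the generating loading pattern within ±0.05 across 20 replicate
seeds.

What the generator does **not** emulate: real German geography, real
indicator marginals, spatial autocorrelation between neighbouring
districts, boundary reforms, and population migration between regions.
Passing tests on synthetic data therefore demonstrate the correctness of
the estimators under the stated generative model, not the validity of
the published index on real data.

## Epidemiological linkage

* **Direct age standardization** uses the 2013 European Standard
  Population, shipped as a plain-text table in 5-year groups (0–4
  combined, 90+ collapsed; weights sum to 100,000):
  $\mathrm{rate} = 10^5 \sum_a w_a (c_a/p_a) / \sum_a w_a$. Zero
  population with nonzero counts is an error; empty cells are dropped
  with a warning.
* **Quintile-group rate trends** collapse quintiles to low/mid/high,
  sum events and person-years by group, sex, year and age, standardize,
  and report absolute and relative first-to-last-year declines.
* **Multilevel Poisson rate ratios** model counts on age-group effects
  and quintile indicators with a log person-years offset and a
  district-level random intercept (lme4's Poisson GLMM); "second level
  units" admits several structures, and the random intercept is the
  simplest. Sexes are modelled separately; intervals are Wald on the log
  scale (95% default). With `random_intercept = FALSE` the model reduces
  to a Poisson GLM whose single-stratum two-district case reproduces the
  hand-computed ratio exactly — the cross-check the tests use.
* **Gradient regression** fits a district outcome on the index by least
  squares; since the index spans [0, 1], the slope *is* the estimated
  outcome difference between the least and most deprived district, and
  the adjusted R² reports the share of regional variation accounted for.

When external outcome data are linked to the index, the usual design
joins them to a single reference index year; the epi functions and the
outcome generator treat single-year score inputs as time-constant
linkage. Linking to yearly re-assigned quintiles attenuates gradient
estimates through quintile churn (regression to the mean), which the
time-constant design avoids.

The real-data magnitudes quoted in the documentation (life-expectancy
gaps of 6.0 and 3.2 years, top-quintile rate ratios of 1.46 and 1.23,
cardiovascular rate declines around 45%) require external registry,
cause-of-death and life-expectancy inputs and are *not* reproduced by
this package; they serve as the programmed effect sizes of the
synthetic-outcome generator, and the tests verify their recovery within
simulation confidence intervals.

## Numerical choices and degenerate inputs

* Min-max normalization errors on constant scores within a year rather
  than dividing by zero.
* Quintile ties share the lower quintile; the assignment is
  deterministic given the input.
* The break and reform regressions drop the region (or year) fixed
  effect when only one level is present, so single-series fixtures are
  estimable.
* The noiseless random-intercept fit sits on the boundary of the
  variance space; the singular-fit check is disabled for that fit and
  predictions remain exact.
* Problem sizes in the test suite: the default 50-district synthetic
  build (one complete end-to-end run, cached across tests), 20
  loading-recovery replicates at ~5,000 observations, and a
  200-district imputation simulation — chosen as the smallest designs
  at which each statistical claim is sharp.
* All correction estimators store their fitted models, so every
  transformation of an observed cell is reconstructible from the
  correction ledger plus the models.

## Known limitations

* The index is relative *within* each level-year: scores are not
  comparable across years in absolute terms (a region can keep its raw
  situation and change score because the distribution moved). This is
  inherent to the yearly min-max design.
* The East–West and break corrections assume additive, time-constant
  artefacts; a drifting reporting artefact would require an interaction
  the package does not fit.
* The bimodality flag is a pragmatic KDE mode count, adequate for the
  pronounced two-cluster pattern it guards against, but it is not a
  formal test with calibrated size.
* GVB-level scores rest on three of nine indicators (flagged
  `uncertain`); treat sub-district contrasts accordingly.
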