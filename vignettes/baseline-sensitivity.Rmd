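---
title: "How deforbase quantifies baseline sensitivity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{How deforbase quantifies baseline sensitivity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(deforbase)
```

## The problem

Jurisdictional avoided-deforestation crediting issues carbon credits against
a *deforestation emission baseline*: the business-as-usual annual emissions
of a national or subnational jurisdiction, defined as

$$B = \hat{D} \times C,$$

where $\hat{D}$ is a projected deforestation rate (km²/yr) and $C$ is the
average forest carbon density (tCO₂e/km²). Crediting standards permit many
defensible choices for both factors — which forest-change dataset to use,
how long a historical reference period, which projection method, which
biomass and soil-carbon sources — and every choice yields a different
baseline and hence a different number of credits. `deforbase` enumerates the
grid of permitted combinations, computes a baseline for each, and
quantifies the consequences of the choices: the spread of baselines
(coefficient of variation), their hindcast accuracy (forecast error), their
propagated uncertainty, and which choice matters most (random-forest
variable importance).

## Projection approaches

Seven approaches are implemented, in three families:

1. **Historical average** (`hist`): the arithmetic mean annual rate of the
   reference window, continued forward. It is a pure summary statistic, so
   no model-based prediction interval is attached; `hist` combinations are
   excluded from uncertainty summaries and flagged as such.
2. **Time functions** (`linear`, `poly2`): least-squares polynomials of the
   annual rate on year, degree 1 or 2, extrapolated over the future window
   of the same length as the reference window. The point projection is the
   *mean* of the fitted curve over that future window, and the 90%
   prediction interval is the interval for that mean of future observations
   (coefficient variance plus residual variance shrunk by the horizon
   length). Projecting the mean rather than the endpoint was a design
   choice: baselines are annualised quantities, and the mean is the
   quantity multiplied into emissions.
3. **Driver models** (`global`, `regional`, and their random-subset
   ensembles `global_s`, `regional_s`): linear regressions of the
   per-jurisdiction mean annual rate over the window on up to twelve
   biophysical and socioeconomic covariates (elevation, slope, temperature,
   precipitation, GDP, HDI, nightlights, population density, and forest /
   agriculture / mining / plantation shares), fitted either on all
   jurisdictions or per world region (Africa, Asia, Oceania, Latin America,
   North America, Europe).

Driver-model fitting pipeline, in order:

- **Response**: the window-mean annual deforestation rate per jurisdiction.
  Pooling per-year rates was the alternative reading; the window mean is
  used because the projected quantity is itself a window-level rate.
- **Box-Cox transform** with the power chosen by maximum profile likelihood
  on the candidate design (grid −2…2, step 0.01, via `MASS::boxcox`). Rates
  of exactly zero are handled by adding an offset of half the smallest
  positive response before the transform; the offset is recorded and
  subtracted after back-transform, then the rate floored at zero. Each fit
  (including each regional fit and each ensemble member) chooses its own
  lambda.
- **Outlier removal**: one pass; observations with |studentized residual| >
  3 in the preliminary full fit are dropped.
- **Bidirectional stepwise elimination** by AIC (`stats::step`), starting
  from the full supplied driver subset with the intercept-only model as the
  lower scope. If elimination removes every driver the intercept-only model
  is kept: it still defines a valid (mean) prediction.
- **Prediction intervals** at the 90% level are computed on the transformed
  scale and back-transformed through the monotone inverse, which preserves
  the ordering lower ≤ point ≤ upper. For negative Box-Cox powers the
  inverse saturates: values beyond the transform's image map to +Inf and
  the result is flagged invalid rather than silently truncated.

The **ensemble** approaches fit `reps` models (default 300, desk-scale
configurations use fewer), each on a driver subset whose size is drawn
uniformly from 3–11, sampled without replacement. The ensemble point is the
mean of member back-transformed predictions; the 90% interval is the
5th–95th percentile of member points (the member spread is the only
uncertainty the ensemble exposes; the interval construction is a design
choice). Members whose fit fails — under-determined or singular designs —
are dropped and counted; more than 50% failures aborts the cell.

Projected rates below zero would be rejected in real submissions, so
`screen_nonnegative()` flags them invalid and excludes them from every
downstream statistic (they are retained in the record table for audit, not
clamped to zero). For valid results the interval's lower bound is floored
at zero.

## Carbon densities

Average forest carbon combines aboveground biomass (AGB), belowground
biomass (BGB) and soil organic carbon (SOC). Biomass converts to carbon by
the stoichiometric factor 0.47 and carbon to CO₂-equivalent by the molar
ratio 3.67; SOC is already carbon, so only the molar factor applies. The
belowground pool decays slowly after deforestation; a conservative 10-year
decay is represented as a weight `min(1, horizon/10)` on BGB, with the
default 10-year horizon counting it in full. Whether SOC should be decay
weighted, and over what horizon, is not settled; both are configuration
knobs (`soc_weight`, `horizon_years`) defaulting to full counting. BGB can
be observed directly or derived from AGB by region-specific root:shoot
ratios; in that case the product's relative uncertainty combines the AGB
and ratio uncertainties in quadrature.

Per-pool relative uncertainties come from the data provider when available
and otherwise default to 33%. Pool uncertainties combine by summation in
quadrature weighted by contribution:
$u = \sqrt{\sum_i (c_i u_i)^2} / \sum_i c_i$, and the projection and carbon
uncertainties of a baseline combine as $\sqrt{u_D^2 + u_C^2}$. Both
identities are verified against Monte-Carlo propagation oracles in the test
suite.

## The method grid

The grid crosses projection approach (7) × forest dataset (5: three
tree-cover-threshold variants of one high-resolution product spanning
2000–2021, plus two coarser land-cover products spanning 2001–2020 and
1992–2020) × reference length (5–15 yr) × admissible start year × carbon
forest mask (5) × AGB source (3) × BGB source (3) × SOC source (2). A
window is admissible when it fits entirely inside the variant's span;
annual loss is observable from the year *after* the first mapped year,
since each year's forest is clipped to the previous year's to admit only
loss. At full scale this grid reaches the 10⁹ order of combinations across
a realistic cohort of ~2,800 jurisdictions — which is why the package's
defaults thin the start years and reference lengths to desk scale (the full
grid remains expressible through `grid_config()`). Whether the
deforestation dataset and the carbon mask cross fully is not fixed by
convention; the grid crosses them fully, since the two uses are
independent choices.

Driver models are fitted once per (approach, scope, dataset, window) cell
and predictions reused across jurisdictions.

## Metrics

- **Relative variability**: CV = 100 × sample SD / mean over a
  jurisdiction's valid baselines — overall, and per level of each grid
  parameter (all other parameters free).
- **Hindcast forecast error**: a projection fitted on a reference window is
  scored against the observed mean rate of the ensuing window of equal
  duration, as |predicted − actual| / actual. Windows whose ensuing period
  is unavailable are skipped; records with zero actual rate are excluded
  with a reason code rather than assigned infinite error. Summaries take
  the median across methods per jurisdiction, then the median (and central
  90% interval, read as the 5th–95th percentile) across jurisdictions.
- **Uncertainty summaries**: per jurisdiction and component (baseline,
  projection, carbon, AGB-carbon, BGB-carbon), the median relative
  uncertainty and the fraction of methods exceeding a threshold (default
  15%, the level above which crediting standards typically require a
  discount).
- **Level comparisons**: one-way ANOVA with Tukey HSD post-hoc tests on
  per-jurisdiction level statistics, treating jurisdiction-level values as
  independent observations per level. That pooling choice matches how such
  comparisons are usually reported; the resulting degrees of freedom
  reflect jurisdictions × levels.
- **Variable importance**: `n_models` random forests (`ranger`, permutation
  importance on out-of-bag rows, unordered factors handled by
  response-ordering), each on a random row subsample without replacement
  ("bootstrap" here refers to the repeated model fits); means and standard
  errors are taken across models. Published-scale settings are 100 models ×
  200 trees × 900,000 rows; the desk-scale defaults are 20 × 50 × 50,000,
  with the full scale reachable by configuration. Start year can be added
  as a predictor by flag, default off, matching the convention of ranking
  only the parameters a methods reviewer chooses directly.

## The synthetic generator

Real inputs are decades of global rasters; the generator replaces them with
seeded cohorts whose ground truth is known, so every stage is testable
offline. Per jurisdiction the latent log deforestation rate is

$$\log D_t = \log(f \cdot F_0) + \mathbf{x}_t' \boldsymbol\beta + \eta_t,$$

with $f$ the baseline annual loss fraction (default 0.005), $F_0$ the
initial forest area (lognormal, median 5,000 km², log-sd 0.8), twelve
standardised drivers of which four have nonzero effect by default (GDP
+0.40, population density +0.30, slope −0.25, agriculture share +0.20),
and $\eta_t$ an AR(1) with coefficient 0.4 and marginal sd 0.15 — values
chosen once as plausible for national deforestation series, not calibrated
to any dataset. Each of five dataset variants observes the latent rate
through a multiplicative bias (0.85–1.15) and mean-preserving lognormal
noise (CV 0.10–0.20), then clips each year's loss to the forest remaining
the previous year. Setting `area_noise_exponent = 0.5` makes observation
CVs scale as $1/\sqrt{F_0}$, emulating pixel-counting estimators that are
relatively noisier over small areas. Every national jurisdiction also gets
level-1 children that partition its latent series by a Dirichlet share
vector, so the screening rules (≥1,000 km² forest to enter; >10,000 km²
split into subnational units; <10% forest cover excluded) can be exercised.
All randomness derives from one root seed through named streams, so adding
jurisdictions never changes existing ones and regeneration is bit-identical.

Carbon truth is drawn per jurisdiction (AGB lognormal around 150 Mg/ha,
SOC around 80 Mg C/ha, BGB a region-specific root:shoot ratio of AGB);
dense sources observe truth × mask factor × source bias, while a sparse
lidar-like source simulates 1,000 equal-area cells, samples a fraction
(default 5%) without replacement and reports the sample mean with its
uncertainty inflated by the finite-population standard error.

What the generator does *not* emulate: spatial autocorrelation, real
covariance among forest datasets (the bias-plus-independent-noise structure
is an assumption), regime shifts in deforestation, or forest gain. Passing
tests therefore demonstrate that the machinery is correct and that the
qualitative findings carry over from the assumed statistical structure —
not that any particular real-world number is reproduced.

## Numerical choices and degenerate inputs

- Constant responses skip the Box-Cox profile (lambda fixed at 1) and
  stepwise elimination; predictions reduce to the constant with zero-width
  intervals.
- Fits require at least (number of drivers + 5) jurisdictions with positive
  mean rate; smaller scopes raise a fit error, which the grid engine
  records as invalid cells rather than aborting the run.
- Quadrature with zero total contribution is undefined and returned as
  `NA` with a flag.
- Zero actual rates in hindcasts are excluded, with exclusion reasons kept.
- CVs are undefined (NA) for non-positive means.

## Desk-scale problem sizes

The bundled example configuration runs 20 national jurisdictions (plus
children), two reference lengths, one start year per window and 10-member
ensembles — about a minute end to end. The test suite uses cohorts of
25–200 jurisdictions and ensembles of 15–50 members; the acceptance script
uses 80 nationals, three reference lengths, two start years and 15-member
ensembles. These sizes were chosen so that distributional checks (parameter
recovery, ANOVA calibration, importance ordering) are stable under their
stated tolerances.

## Known limitations

- Regional driver models need ≥17 jurisdictions per region for the full
  12-driver design; small synthetic cohorts therefore produce invalid
  regional cells (as they would for small real regions).
- The `hist` approach carries no uncertainty by construction, so
  uncertainty summaries describe the model-based methods only.
- The generator's independence assumptions make per-level CV contrasts
  cleaner than they would be on real, strongly correlated datasets.
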