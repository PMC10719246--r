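# deforbase

Sensitivity analysis of jurisdictional deforestation emission baselines.

Avoided-deforestation carbon crediting (REDD+ and the voluntary market)
issues credits against a business-as-usual **baseline**

> B (tCO₂e/yr) = projected deforestation rate (km²/yr) × average forest
> carbon density (tCO₂e/km²)

for a national or subnational jurisdiction. Standards permit many
defensible choices for both factors: the projection approach (historical
average `hist`; linear and quadratic time functions `linear`, `poly2`;
global and regional driver regressions `global`, `regional` and their
300-member random-subset ensembles `global_s`, `regional_s`), the forest
dataset (five variants with different spans and tree-cover thresholds), the
historical reference period (5–15 years, any admissible start year), and
the carbon sources (forest mask × 3 AGB × 3 BGB × 2 SOC). `deforbase`
enumerates this grid, computes a baseline with a quadrature-propagated
relative uncertainty for every valid jurisdiction × combination, and
summarises the spread:

- **relative variability** — CV = 100 × SD/mean across method combinations,
  overall and per level of each parameter, compared by one-way ANOVA with
  Tukey HSD;
- **hindcast forecast error** — |predicted − actual| / actual against the
  window following the reference period;
- **uncertainty summaries** — medians and the fraction of methods exceeding
  a threshold (default 15%, where standards require discounts), built from
  90% prediction intervals, provider or 33%-default carbon uncertainties,
  and summation in quadrature;
- **variable importance** — bootstrapped random-forest permutation
  importance of the grid parameters.

The data inputs of a real analysis are decades of global rasters; the
package ships a seeded **synthetic jurisdiction generator** with known
ground truth (latent driver-driven deforestation, biased/noisy dataset
variants, multi-source carbon layers including a sparsely sampled
lidar-like source, subnational children, screening rules) so the entire
pipeline runs and is tested offline. See the methods vignette
(`vignettes/baseline-sensitivity.Rmd`) for the model details and design
choices.

## Worked example

```r
library(deforbase)

cfg  <- generator_config(n_jurisdictions = 12, seed = 3, n_children = 2)
sim  <- screen_jurisdictions(generate_panels(cfg))
carb <- generate_carbon_layers(cfg, sim)

gcfg <- grid_config(ref_lengths = c(5, 10), n_start_years = 1,
                    ensemble_reps = 5)
bl   <- run_grid(sim, carb, gcfg, seed = 9)

overall_variability(bl)
#> # A tibble: 10 × 3
#>    jurisdiction_id cv_percent n_methods
#>    <chr>                <dbl>     <int>
#>  1 J0001                 65.0      2880
#>  2 J0002                 47.7      2520
#>  3 J0003                 41.1      2880
#>  # …
```

Each row is one jurisdiction: `cv_percent` says its baseline varies by
that percentage of its mean across the `n_methods` valid method
combinations — methodological freedom alone moves this jurisdiction's
baseline by roughly half of its value. Downstream:

```r
per_level_variability(bl, "approach")      # CV fixing each approach
uncertainty_summaries(bl, threshold = 15)  # medians + exceedance fractions
variable_importance(bl, seed = 1)          # which parameter matters most
```

Or run everything (simulate → project → carbon → grid → metrics →
importance → report) from one config:

```r
run_pipeline(system.file("extdata", "config-small.yml", package = "deforbase"),
             out_dir = "out")   # writes CSVs + report.md + run_manifest.json
```

A thin CLI wrapper for shell use is in `inst/scripts/baseline-ensemble.R`.

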