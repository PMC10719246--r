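# Example pipeline configuration: a small 20-jurisdiction cohort with a
# thinned method grid, sized so a full run completes in about a minute.
# Keys under `generator` are passed to generator_config(), keys under
# `grid` to grid_config(); omitted keys take the package defaults.
seed: 1

generator:
  n_jurisdictions: 20
  n_children: 4
  # observation noise CV of small jurisdictions is inflated as
  # 1/sqrt(forest area) when this exponent is 0.5; 0 disables the scaling
  area_noise_exponent: 0.5

grid:
  ref_lengths: [5, 10]
  n_start_years: 1
  ensemble_reps: 10

screening:
  reference_variant: modis

metrics:
  uncertainty_threshold: 15

importance:
  n_models: 10
  n_trees: 50
  sample_rows: 20000
  include_start_year: false
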