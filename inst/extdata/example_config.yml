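# Example pipeline configuration (synthetic mode).
# Run with:
#   cfg <- read_pipeline_config(system.file("extdata", "example_config.yml",
#                                           package = "rangecast"))
#   res <- run_pipeline(cfg)
synthetic:
  n_rows: 80
  n_cols: 80
  cell_size_km: 5
  n_presences: 250
  n_analogues: 800
  niche:
    intercept: -1
    coefficients: {bio13: 4, bio15: -3, bio18: 2}
    quadratic_coefficients: {bio13: -1.5}
  scenarios:
    past: {additive_delta: {bio15: 0.6, bio13: -0.3}}
    future: {additive_delta: {bio13: 0.25, bio18: 0.25}}
thin_dist_km: 30
pa_min_dist_km: 30
vif_threshold: 10
n_repeats: 6
gates: {tss: 0.7, auc: 0.9, kappa: 0.7}
seed: 11
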