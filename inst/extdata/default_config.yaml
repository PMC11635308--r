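# Default three-species scenario: optima bracketing the 37 degC reference
# environmental maximum, right-skewed beta curves normalized to peak 1,
# equal carrying capacities, equal 1% initial densities.
seed: 1
community:
  - species_id: S3
    t_min: 0
    t_opt: 32
    t_max: 37
    r_peak: 1
    death_slope: 0.1
    form: beta
    k: 1
    n0: 0.01
  - species_id: S1
    t_min: 0
    t_opt: 37
    t_max: 41
    r_peak: 1
    death_slope: 0.1
    form: beta
    k: 1
    n0: 0.01
  - species_id: S2
    t_min: 0
    t_opt: 42
    t_max: 46
    r_peak: 1
    death_slope: 0.1
    form: beta
    k: 1
    n0: 0.01
sweep:
  t_start: 25
  t_end: 45
  step: 0.1
control:
  deriv_tol: 1.0e-9
  horizon: 1.0e4
  extinction_tol: 1.0e-9
  rtol: 1.0e-8
  atol: 1.0e-12
tie_tol: 1.0e-6
scenarios:
  skew_range: [0.05, 0.8]
  spacing_range: [2.0, 8.0]
  r_peak_range: [0.5, 1.5]
  normalize: true
  axes: [skewness, spacing, normalization]
  n_draws: 10
  include_pairwise: true
  spacing_scale: linear
output_dir: thermocompete_out
log_level: info
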