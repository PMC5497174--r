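# Example pipeline configuration for run_scenarios(); every key falls
# back to the package default (see load_config()).
seed: 42
n_core: 11400
scenarios:
  - estimated
  - fixed2
  - fixed1.1
  - none
  - cvd-freeze
trend_method: joint
z_impairment_threshold: -1.5
iqcode_cut: 3.6
true_incidence_trend_or: 0.973
n_draws: 1000
base_year: 2006
horizon_year: 2040
standard_population_year: 2015
cvd_freeze_year: 2014
psa: false
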