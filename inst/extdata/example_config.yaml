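# Example ribostruct pipeline configuration.
# `seed` is required; `simulate` passes options to sim_config();
# `thresholds` override the documented analysis defaults.
seed: 42
simulate:
  n_pairs: 20
  mean_len: 400
thresholds:
  alpha: 0.05
  min_coverage: 50
  fold_window: 300
  fold_step: 150
  ribosnitch_window: 50
  min_effect: 0.1
  decile: 0.1
  reference_pop: DW
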