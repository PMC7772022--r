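# Example pipeline configuration (see read_pipeline_config()).
seed: 7
cohort:
  n_fractured: 20
  n_control: 12
sim:
  target_elements: 3000
split:
  n_runs: 50
smote:
  target_per_class: 200
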