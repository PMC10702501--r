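# Demonstration pipeline configuration: the study's design structure at a
# reduced respondent count so the full pipeline runs in seconds.
mode: simulate
seed: 7
design:
  n_tasks: 36
  n_blocks: 3
  n_sweeps: 3
  repeat_position: 3
simulation:
  n_respondents: 90
  utility_scale: 0.04
  sigma: 0.8
  optout_rate: 0.05
estimation:
  n_draws: 80
metrics:
  kr_draws: 400
subgroup:
  covariate: has_caregiver
  group1_values: [1]
  labels: [no_caregiver, caregiver]
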