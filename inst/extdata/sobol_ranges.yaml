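# Hyperparameter ranges for the variance-based sensitivity analysis,
# shipped verbatim as published. NOTE: some ranges appear inconsistent with
# the baseline values (gamma baseline 2.85 vs range [0.2, 0.5]; nu baseline 1
# vs range [2, 3]); they are reproduced as printed. A "plausible" variant
# reassigning gamma -> [2, 3] and nu -> [0.2, 0.5] is provided for users.
as_published:
  N_terms_stage2: [300, 500]
  N_terms_stage3: [200, 400]
  l_fr:   [0.1, 0.9]
  delta:  [0.1, 0.9]
  eta:    [0.2, 0.5]
  gamma:  [0.2, 0.5]
  nu:     [2, 3]
  theta_min: [0, 72]
  f_n:    [0, 5]
  N_seeds_SVP: [300, 700]
plausible:
  N_terms_stage2: [300, 500]
  N_terms_stage3: [200, 400]
  l_fr:   [0.1, 0.9]
  delta:  [0.1, 0.9]
  eta:    [0.2, 0.5]
  gamma:  [2, 3]
  nu:     [0.2, 0.5]
  theta_min: [0, 72]
  f_n:    [0, 5]
  N_seeds_SVP: [300, 700]
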