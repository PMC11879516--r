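# Small end-to-end example: 50 subjects, one week of 8 daily signals,
# a weak differential-susceptibility truth acting on paranoia via the
# positive-context appraisal through the most inclusive PRS threshold.
seed: 2026
synth:
  n_subjects: 50
  n_blocks: 10
  snps_per_block: 8
  block_corr: 0.7
  prop_causal: 0.3
  beta_sd: 0.1
  compliance: 0.727
  true_outcome: paranoia
  true_context: positive
  true_params:
    b0: 2.0
    s0: -0.15
    s1: -0.2
    c: 4.5
    sigma_u: 0.3
    sigma_e: 0.5
  item_noise_sd: 0.25
plan:
  alpha: 0.05
prs:
  r2_max: 0.1
  window_kb: 1000
n_boot: 100
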