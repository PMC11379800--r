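# Calibrated analysis parameters for detecting a standardized effect of
# d = 0.2 with ~80% pairwise power and a pairwise false-positive rate < 5%.
design:
  n_min: 150
  n_max: 450
  bf_fail: 0.2
  bf_success: 3
  rscale: 0.5
  step: 1
seed: 1
n_reps: 10000
scenario:
  effect_grid: [-0.2, -0.1, 0.0, 0.1, 0.2, 0.3, 0.4, 0.5]
  checkpoints: [150, 200, 250, 350, 450]
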