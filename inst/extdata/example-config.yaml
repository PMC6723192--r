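# Example run configuration: DUSP8 induced by ERK1/2, study d5 grid.
topology: ERK12
d5_grid: [1, 10, 20, 50, 100, 500]
solver:
  n_points: 501
synthetic:
  seed: 1
  noise_sd: 0.05
  n_reps: 2
out_dir: duspkin-erk12-run
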