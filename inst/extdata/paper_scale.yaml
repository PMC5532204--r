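# Study-scale run: 149/95/112 cells, the full 20-threshold grid, all three
# tasks. The exhaustive search over 183,210 subsets x 5 folds takes on the
# order of an hour per task on one core.
seed: 0
cohort:
  B: 149
  CD4T: 95
  CD8T: 112
grid:
  shape: [96, 96, 96]
  pitch: 0.1
thresholds:
  from: 1.340
  to: 1.378
  by: 0.002
tasks: [b_vs_t, cd4_vs_cd8, multiclass]
classifier:
  k: 4
  folds: 5
train_fraction: 0.7
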