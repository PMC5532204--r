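# Desk-scale smoke run: 15 cells, 2 thresholds, one task.
seed: 5
cohort:
  B: 5
  CD4T: 5
  CD8T: 5
grid:
  shape: [48, 48, 48]
  pitch: 0.2
thresholds:
  from: 1.340
  to: 1.368
  by: 0.028
tasks: [b_vs_t]
classifier:
  k: 4
  folds: 3
train_fraction: 0.7
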