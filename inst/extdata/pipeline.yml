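seed: 7
thresholds: [1.0, 0.99, 0.98]
min_area: 0.05
similarity_cut: 0.93
bootstrap_reps: 100
community:
  n_isolates: 66
  divergence_within_genus: 0.01
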