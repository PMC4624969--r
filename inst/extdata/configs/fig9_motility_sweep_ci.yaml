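# Invasion probability vs mutant motility at wide mutant fitness spread
# (uniform on [0, 3]); motility amplifies invasion where heterogeneity
# suppresses it.
lattice: {rows: 21, cols: 21}
fitness_A: {kind: constant, mean: 1.0}
fitness_B: {kind: uniform, mean: 1.5, width: 1.5}
motility: {m_A: 0.0, m_B: 0.0}
protocol: {n_iters: 500, n_configs: 3, seed: 1, verbose: true}
sweep:
  variable: m_B
  values: [0.0, 1.0, 5.0]
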