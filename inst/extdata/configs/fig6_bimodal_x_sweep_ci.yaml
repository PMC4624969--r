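# Invasion probability vs fraction x of advantaged sites for a bimodal
# mutant fitness field {0.5, 1.5}; zero below the connectivity threshold.
lattice: {rows: 21, cols: 21}
fitness_A: {kind: constant, mean: 1.0}
fitness_B: {kind: bimodal, r1: 0.5, r2: 1.5, x: 0.5}
motility: {m_A: 0.0, m_B: 0.0}
protocol: {n_iters: 500, n_configs: 3, seed: 1, verbose: true}
sweep:
  variable: x
  values: [0.25, 0.5, 0.75, 1.0]
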