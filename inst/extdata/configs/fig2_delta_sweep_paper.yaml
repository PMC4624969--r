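# Invasion probability vs distribution width for advantageous mutants,
# at the full protocol scale (10000 runs per quenched configuration).
lattice: {rows: 21, cols: 21}
fitness_A: {kind: constant, mean: 1.0}
fitness_B: {kind: uniform, mean: 1.5, width: 0.0}
motility: {m_A: 0.0, m_B: 0.0}
protocol: {n_iters: 10000, n_configs: 10, seed: 1, verbose: true}
sweep:
  variable: delta
  values: [0.0, 0.25, 0.5, 0.75, 1.0, 1.25, 1.5]
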