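# Structured-grid neutral benchmark: homogeneous r_A = r_B = 1, no motility.
# The fixation fraction should sit near the space-free value 1/N = 1/441.
lattice: {rows: 21, cols: 21}
fitness_A: {kind: constant, mean: 1.0}
fitness_B: {kind: constant, mean: 1.0}
motility: {m_A: 0.0, m_B: 0.0}
protocol: {n_iters: 2000, n_configs: 1, seed: 1, verbose: true}
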