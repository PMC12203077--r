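# Example data

`toy/` is a small synthetic dataset produced by the package's own
hierarchical ZINB generator (`generateDataset(M = 5, nSim = 8, nCell = 12,
f = 1.5, density = 0.2, seed = 2024)`), stored in the text formats the
command-line tool reads: Matrix Market counts, id files, cell and
individual metadata, and the ground-truth table.  It exists for examples
and smoke tests, not for benchmarking.
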