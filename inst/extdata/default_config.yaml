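seed: 1337.0
flank_bp: 1200.0
pseudocount: 0.01
basis: spikein
binsize: 50.0
fragment_length: 200.0
window_bp: 5000.0
base:
  genome_length: 500000.0
  n_chroms: 1.0
  n_peaks: 20.0
  peak_width_range:
  - 2000.0
  - 5000.0
  ip_depth: 120000.0
  input_depth: 120000.0
  spikein_depth: 40000.0
  spike_genome_length: 50000.0
  n_genes: 40.0
conditions:
  wt: []
  ezh2ko:
    decay_length: 0.0
    global_level: 0.3
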