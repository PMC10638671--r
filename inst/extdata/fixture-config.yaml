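# packaged end-to-end fixture: 1200 simulated peaks, three stages
simulation:
  n_peaks: 1200
  n_genes: 400
  chrom_length: 24000000
  effect: 1.5
  baseline_mean: 300
  dispersion: 0.05
  trans_dominance: 0.5
  coupling_odds: 3
  base_rate: 0.2
alpha: 0.05
min_cpm: 3
min_fraction: 0.33333333
window_bp: 25000
proximal_bp: 500
seed: 42
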