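# Demo configuration for run_all(): a small, fully simulated worm experiment
# with a fly spike-in. Equivalent to default_config(seed = 1).
seed: 1
outdir: xrquant_demo_out
simulate: true
species: worm
spike_species: fly
simulation:
  genome_sizes:
    chr1: 150000
    chrM: 12000
  n_genes: 25
  gene_length_range: [1000, 4000]
  intergenic_gap: 400
  n_reads: 8000
  signal_fraction: 0.9
  tcr_ratio: 4.0
  mito_fraction: 0.05
  duplicate_rate: 0.2
  spike_reads: 1500
  dilutions: [1.0, 0.1, 0.01]
spike_simulation:
  genome_sizes:
    spike1: 40000
  n_reads: 4000
  mito_fraction: 0.0
  signal_fraction: 0.95
window: [4, 10]
top_n: 5000
k: 20
mutant_relative: 0.01
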