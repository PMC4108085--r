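# Demo MSCC pipeline configuration: a small simulated experiment with
# read-level simulation, mapped and quantified end to end.
seed: 1
simulate:
  enabled: true
  scenario: "null"      # all five samples share one methylome
  read_level: true      # emit FASTQ and exercise demultiplex + tag matching
  n_chroms: 1
  chrom_length: 20000
  mean_depth: 35
  spike_in_mean: 500
  seq_error_rate: 0.001
analysis:
  min_depth: 30         # the "30+ reads" site filter
  window_width: 200
  min_sites: 4          # "> 3 sequenced CpGs" per analysis unit
  delta_cutoff: 0.25    # the 25% methylation-change rule
  q_cutoff: 0.05
  shore_width: 2000
  tss_halfwidth: 1000
  flank: 2000
  tag_length: 18
  max_mismatch: 1       # "fewer than 2 mismatches"
  baseline: S0h
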