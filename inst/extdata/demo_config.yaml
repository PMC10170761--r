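# Small demonstration configuration: a 4 Mb two-chromosome genome with 300
# genes, a 30-gene consistent DE core (18 down / 12 up), and all analysis
# stages at their default thresholds.
seed: 7
simulation:
  n_chroms: 2
  chrom_length: 2000000
  n_genes: 300
  de_core_size: 30
  de_core_down: 18
peaks:
  tss_window: 1000
  broad_threshold: 0.25
  region_merge_gap: 1000
  pseudocount: 0.5
profiles:
  flank: 2000
  bin: 50
  body_bins: 100
expression:
  alpha: 0.05
qpcr:
  ip_channel: H3cs1
  h3_channel: H3
  ref_condition: WT
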