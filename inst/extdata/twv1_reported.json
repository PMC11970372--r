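{
  "collapsed_total_bp": 218000000,
  "w_region_chrom": "chr12_h2",
  "w_region_start": 0,
  "w_region_end": 30000000,
  "w_unaligned_bp": 10000000,
  "z_region_chrom": "chr12_h1",
  "z_region_start": 0,
  "z_region_end": 16000000,
  "z_unaligned_bp": 4000000,
  "cyp725a_in_cluster": 54,
  "cyp725a_total": 64,
  "repeat_pct_of_genome": 84,
  "ltr_pct_of_repeats": 69
}
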