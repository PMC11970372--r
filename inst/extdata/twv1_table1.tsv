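assembly	qv	contig_n50_mb	genome_size_bp	gap_count
TWv0	19.3585	8.6	11119083473	8004
TWv1	59.5658	169.4	20348291365	201
TWv1-hap1	60.1364	213.7	9868113160	85
TWv1-hap2	60.7947	136.6	9979816178	116
TCv0	NA	2.44	10232176133	12092
TYv0	NA	2.89	10737203084	11130
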