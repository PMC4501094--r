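quantity	value
raw_reads	151340419
unique_reads	1162917
mito_trf_reads	12240
nuclear_trf_reads	5048874
nuclear_to_mito_fold	412
gly_gcc_pct_of_nuclear	72.9
gly_ccc_pct_of_nuclear	14.8
ser_gcu_pct_of_mito	30.1
n_mito_trf_anticodons	16
n_nuclear_trf_anticodons	39
n_nuclear_rows_5half	12
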