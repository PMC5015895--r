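quantity	value
raw_snp_total	13775885
n_bulls	18
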