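breed	n_bulls	raw_avg	filt90_avg	filt100_avg
Hereford	6	754719	34658	30052
PolishHF	6	880442	39730	31978
PolishRed	6	660819	25414	20573
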