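breed	age_months	total_reads	mapped	properly_paired
PolishHF	6	218.45	218.45	202.27
PolishHF	9	159.83	159.83	148.29
PolishHF	12	137.10	137.10	128.94
PolishRed	6	108.49	108.49	102.68
PolishRed	9	56.89	56.89	54.14
PolishRed	12	50.00	50.00	46.48
Hereford	6	207.07	202.72	174.57
Hereford	9	105.39	103.66	82.16
Hereford	12	95.58	94.07	78.77
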