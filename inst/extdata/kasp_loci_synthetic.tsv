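locus	allele_normal	allele_mutant
BTA25_33248237	G	C
BTA16_81545856	T	C
BTA21_68782355	T	C
BTA23_9540557	T	C
BTA10_102942684	A	G
BTA25_37378666	A	G
BTA4_77555734	C	T
BTA19_27086284	G	A
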