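sample_id	BTA25_33248237	BTA16_81545856	BTA21_68782355	BTA23_9540557	BTA10_102942684	BTA25_37378666	BTA4_77555734	BTA19_27086284
BULL01	CC	TC	TT	CC	AG	GG	TT	AA
BULL02	CC	TT	TT	CC	AA	GG	TT	GG
BULL03	CC	TC	CC	TC	GG	GG	CT	AA
BULL04	CC	CC	CC	CC	GG	AA	CT	AA
BULL05	GC	CC	CC	CC	AG	AG	TT	GA
BULL06	CC	CC	CC	TC	GG	AG	TT	GG
BULL07	CC	TC	CC	TC	GG	AG	TT	AA
BULL08	CC	CC	CC	CC	AG	GG	CT	GA
BULL09	CC	TC	CC	CC	GG	GG	TT	AA
BULL10	CC	TC	TC	TC	GG	GG	CT	GG
BULL11	CC	CC	TC	CC	AG	GG	CT	GA
BULL12	GC	TC	TC	TC	AG	GG	TT	GA
BULL13	CC	CC	TC	CC	AG	GG	CC	AA
BULL14	GC	CC	CC	TC	GG	AG	CT	GA
BULL15	CC	CC	TC	CC	AG	AA	CT	GG
BULL16	GC	TC	CC	CC	AG	GG	CT	GA
BULL17	GG	TC	CC	TT	AA	AA	CC	GG
BULL18	GG	TC	--	TC	AA	AA	CC	GG
BULL19	GC	TT	TT	TC	AA	AA	CT	GG
BULL20	GG	TC	TC	TC	AA	AG	CC	GA
BULL21	GC	TT	TT	TT	AA	AG	CC	GA
BULL22	GG	TT	TC	TT	AA	AG	CC	GG
BULL23	GG	TT	TT	TC	AA	AA	TT	GA
BULL24	GG	TT	TT	TT	AG	AA	CC	GG
BULL25	GG	TT	TT	TT	AG	AA	CT	GG
BULL26	GG	TT	TT	TT	AG	AA	CC	AA
BULL27	GG	TT	TT	TT	AA	GG	CC	GG
BULL28	GG	TT	TT	CC	AA	AA	CC	GG
BULL29	GG	TT	TC	TC	--	AA	CC	GG
BULL30	GC	TT	TT	TC	--	AA	CC	GG
BULL31	GC	TC	TT	TC	AA	AG	CC	GG
BULL32	GG	TT	TC	TT	AA	AA	CT	GG
BULL33	GG	TT	TT	TT	AA	AA	CT	GG
BULL34	GG	TT	TT	TT	GG	AA	CC	GG
BULL35	GC	TT	TT	TT	AA	AA	CT	GG
BULL36	GG	TT	TT	TT	AG	AG	CT	GG
BULL37	GG	TT	TT	TT	AA	AA	CC	GA
BULL38	GG	TT	TT	TT	AG	AA	CC	GG
BULL39	GG	TT	TC	TC	AA	AG	CT	GG
BULL40	GG	TT	TC	TT	AA	AA	CC	GG
BULL41	GC	CC	TT	TC	AG	AA	CC	GG
BULL42	GC	TC	TT	TT	AA	AG	CC	GA
BULL43	GG	TT	TT	TT	AA	AG	CC	GG
BULL44	GG	TT	TT	TT	AA	AA	CC	GA
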