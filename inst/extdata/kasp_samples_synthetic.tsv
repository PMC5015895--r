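sample_id	breed	age_months
BULL01	PolishHF	6
BULL02	PolishHF	9
BULL03	PolishHF	12
BULL04	PolishHF	6
BULL05	PolishHF	9
BULL06	PolishHF	12
BULL07	PolishHF	6
BULL08	PolishHF	9
BULL09	PolishHF	12
BULL10	PolishHF	6
BULL11	PolishHF	9
BULL12	PolishHF	12
BULL13	PolishHF	6
BULL14	PolishHF	9
BULL15	PolishHF	12
BULL16	PolishHF	6
BULL17	PolishRed	9
BULL18	PolishRed	12
BULL19	PolishRed	6
BULL20	PolishRed	9
BULL21	PolishRed	12
BULL22	PolishRed	6
BULL23	PolishRed	9
BULL24	PolishRed	12
BULL25	PolishRed	6
BULL26	PolishRed	9
BULL27	PolishRed	12
BULL28	PolishRed	6
BULL29	PolishRed	9
BULL30	PolishRed	12
BULL31	Hereford	6
BULL32	Hereford	9
BULL33	Hereford	12
BULL34	Hereford	6
BULL35	Hereford	9
BULL36	Hereford	12
BULL37	Hereford	6
BULL38	Hereford	9
BULL39	Hereford	12
BULL40	Hereford	6
BULL41	Hereford	9
BULL42	Hereford	12
BULL43	Hereford	6
BULL44	Hereford	9
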