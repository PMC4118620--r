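compound	target	dose_uM	Ki_uM
3PO	PFK2	2.77777777777778	25
3PO	PFK2	13.75	25
3PO	PFK2	37.5	25
3PO	PFK2	100	25
IA	GAPDH	1.11111111111111	10
IA	GAPDH	5.5	10
IA	GAPDH	15	10
IA	GAPDH	40	10
FX11	LDH	0.888888888888889	8
FX11	LDH	4.4	8
FX11	LDH	12	8
FX11	LDH	32	8
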