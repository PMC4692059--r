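drug	gene	p_printed
5-FU	TBRG4	<=0.001
5-FU	MRPL32	<=0.001
5-FU	CYCS	<=0.001
5-FU	PDCD6	0.01
5-FU	COBL	0.01
5-FU	DDX56	0.01
5-FU	MRPS17	0.01
5-FU	PDS5B	0.03
5-FU	TOMM7	0.03
5-FU	AEBP2	0.04
5-FU	NOD1	0.04
5-FU	MIR1204	0.04
5-FU	RFC3	0.05
L-OHP	PDS5B	<0.005
L-OHP	UBL3	0.01
L-OHP	MTIF3	0.02
L-OHP	CASC8	0.02
L-OHP	XPO4	0.04
L-OHP	GTF3A	0.04
L-OHP	PDCD6	0.04
BEZ235	PDCD6	0.002
BEZ235	MYC	0.01
BEZ235	MRPL32	0.01
BEZ235	TBRG4	0.03
BEZ235	PURB	0.04
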