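node1	node2	combined_score
TRH	GJA1	720
GJA1	TRH	650
TRH	MMP2	510
MMP2	TNC	430
TNC	SCGN	400
SCGN	NPY	610
NPY	TRH	350
TRH	SCGN	950
SCGN	TRH	890
MMP2	SCGN	120
GJA1	NPY	230
TNC	NPY	399
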