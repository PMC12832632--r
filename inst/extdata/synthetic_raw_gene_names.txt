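TRH | TRH_XENLA
GJA1
 mmp2_AMBME
SCGN | SCGN_XENLA
AMEX60DD_000123
tnc_XENTR
NPY
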