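alias	symbol
GRIN2	GRIN2B
ADRBK1	GRK2
KAL1	ANOS1
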