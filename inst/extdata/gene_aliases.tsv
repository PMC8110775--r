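alias	signature_symbol
FAM30A	KIAA0125
BEX3	NGFRAP1
ADGRG1	GPR56
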