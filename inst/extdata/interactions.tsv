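source	target	layer
TP53	MDM2	ppi
TP53	CDKN1A	regulatory
HK1	GPI	metabolic
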