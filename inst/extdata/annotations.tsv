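gene	term
TP53	nucleus
MDM2	nucleus
HK1	cytoplasm
GPI	cytoplasm
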