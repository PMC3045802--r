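gene	t1	t2	t3	t4
TP53	12.1	8.4	0.7	22.0
HK1	55.3	4.9	6.2	9.8
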