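reaction_id	genes	reactants	products
R_HEX1	HK1	glucose;ATP	glucose-6-phosphate;ADP
R_PGI	GPI	glucose-6-phosphate	fructose-6-phosphate
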