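# n_residues=40
start	end	tier
3	7	region
10	10	region
13	15	region
17	18	region
20	20	region
23	29	region
33	38	region
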