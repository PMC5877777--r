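# n_residues=40
start	end	tier
1	4	region
6	8	region
17	22	region
24	24	region
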