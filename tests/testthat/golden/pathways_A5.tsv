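target	found	cost	path
A3	TRUE	0.735821	A5-A6-A3
A4	TRUE	0.853829	A5-A4
A5	TRUE	0	A5
A6	TRUE	0.459212	A5-A6
A7	TRUE	0.989516	A5-A6-A7
A10	TRUE	1.8324	A5-A6-A7-A10
A13	TRUE	0.949164	A5-A6-A13
A14	TRUE	0.940421	A5-A6-A14
A15	TRUE	1.59563	A5-A6-A14-A15
A17	TRUE	0.820034	A5-A6-A17
A18	TRUE	1.32456	A5-A6-A17-A18
A20	TRUE	2.49224	A5-A6-A17-A20
A29	TRUE	4.94813	A5-A6-A3-A37-A34-A27-A28-A29
A37	TRUE	1.46004	A5-A6-A3-A37
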