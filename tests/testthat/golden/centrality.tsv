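residue	bc_raw	bc_norm	L	unreachable_pairs
A1	0.611825	0.000825675	3.02244	0
A2	24.3199	0.0328204	2.46667	0
A3	53.7779	0.0725747	2.10256	0
A4	23.4218	0.0316084	2.52137	0
A5	9.36033	0.012632	2.67051	0
A6	69.9847	0.0944463	2.00705	0
A7	51.5549	0.0695748	2.15	0
A8	5.25866	0.00709671	2.78141	0
A9	8.39326	0.0113269	2.65321	0
A10	23.2298	0.0313492	2.31581	0
A11	0.769148	0.00103799	3.01667	0
A12	12.2249	0.0164979	2.63803	0
A13	74.2293	0.100174	2.01303	0
A14	37.1289	0.0501064	2.35107	0
A15	9.18761	0.0123989	2.69829	0
A16	36.7879	0.0496463	2.18397	0
A17	93.1649	0.125729	1.98034	0
A18	7.77056	0.0104866	2.64722	0
A19	8.34231	0.0112582	2.52991	0
A20	16.4041	0.0221377	2.3938	0
A21	3.24912	0.00438478	2.86581	0
A22	7.78142	0.0105012	2.7188	0
A23	54.0051	0.0728813	2.11111	0
A24	51.8213	0.0699343	2.16774	0
A25	11.0201	0.014872	2.57585	0
A26	33.4589	0.0451537	2.29145	0
A27	73.1033	0.0986549	1.98291	0
A28	28.2247	0.03809	2.3765	0
A29	3.21157	0.0043341	2.7735	0
A30	12.4297	0.0167742	2.48483	0
A31	7.43479	0.0100335	2.72991	0
A32	2.55415	0.0034469	2.90342	0
A33	25.3383	0.0341948	2.35919	0
A34	95.0528	0.128276	1.98312	0
A35	16.167	0.0218178	2.57073	0
A36	13.3011	0.0179502	2.55214	0
A37	94.1757	0.127093	1.96004	0
A38	24.9914	0.0337266	2.29081	0
A39	5.57306	0.007521	2.61004	0
A40	4.25049	0.00573615	2.6547	0
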