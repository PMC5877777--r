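res_i	res_j	correlation	cost	contact_freq
A1	A2	-0.45208	0.793897	0.75
A2	A3	-0.398386	0.920334	0.558333
A1	A4	0.0815055	2.50709	0.516667
A3	A4	0.593813	0.521192	0.875
A2	A5	-0.232366	1.45944	0.533333
A4	A5	0.425781	0.853829	0.816667
A3	A6	0.758351	0.276609	0.575
A5	A6	0.631781	0.459212	0.858333
A4	A7	0.588531	0.530125	0.641667
A6	A7	0.588426	0.530304	0.85
A5	A8	0.35558	1.034	0.558333
A7	A8	0.542304	0.611928	0.85
A8	A9	-0.384237	0.956495	0.808333
A7	A10	-0.430467	0.842885	0.533333
A9	A10	-0.193286	1.64359	0.95
A11	A12	0.30081	1.20128	0.616667
A6	A13	0.612656	0.489952	0.808333
A10	A13	-0.349637	1.05086	0.566667
A12	A13	-0.257998	1.3548	0.541667
A6	A14	0.618036	0.481208	1
A11	A14	-0.150619	1.893	0.525
A13	A14	0.503126	0.686914	0.825
A12	A15	-0.246527	1.40028	0.516667
A14	A15	0.519333	0.65521	0.783333
A13	A16	0.640536	0.44545	0.566667
A15	A16	0.544588	0.607725	0.866667
A2	A17	-0.363939	1.01077	0.75
A3	A17	0.829601	0.18681	0.983333
A6	A17	0.697104	0.360821	1
A14	A17	0.599302	0.511989	0.575
A16	A17	0.607314	0.49871	0.766667
A15	A18	0.555064	0.588673	0.541667
A17	A18	0.603793	0.504523	0.816667
A15	A19	-0.186708	1.67821	0.675
A16	A19	-0.208347	1.56855	0.958333
A18	A19	-0.0537698	2.92304	0.941667
A17	A20	-0.187831	1.67221	0.508333
A19	A20	0.190319	1.65905	0.8
A21	A22	-0.263291	1.33449	0.725
A22	A23	-0.100031	2.30227	0.683333
A16	A24	-0.224566	1.49358	1
A20	A24	0.107866	2.22687	0.658333
A23	A24	0.484311	0.725028	0.716667
A22	A25	-0.0784573	2.5452	0.516667
A24	A25	0.430652	0.842455	0.691667
A25	A26	0.536843	0.62205	0.716667
A13	A27	0.0492395	3.01106	0.975
A24	A27	0.580643	0.543619	0.558333
A26	A27	0.46635	0.76282	0.708333
A25	A28	0.537242	0.621306	0.516667
A27	A28	0.591353	0.525342	0.775
A28	A29	0.135335	2	0.858333
A27	A30	-0.0121326	4.41186	0.516667
A29	A30	0.0487675	3.02069	0.925
A30	A31	-0.231978	1.46111	0.991667
A31	A32	-0.197212	1.62347	0.566667
A7	A33	-0.503761	0.685653	1
A32	A33	-0.0896846	2.41146	0.708333
A26	A34	-0.569367	0.563231	0.516667
A27	A34	-0.551526	0.595067	0.975
A30	A34	-0.0508358	2.97916	0.616667
A31	A34	0.350495	1.04841	0.525
A33	A34	0.669891	0.40064	0.683333
A34	A35	0.722711	0.324746	0.708333
A33	A36	0.708995	0.343906	0.558333
A35	A36	0.635636	0.45313	0.75
A3	A37	-0.484701	0.724223	1
A7	A37	-0.446118	0.807172	0.558333
A34	A37	0.692342	0.367675	0.533333
A36	A37	0.636869	0.451192	0.733333
A23	A38	-0.518337	0.657129	1
A37	A38	0.686694	0.375866	0.775
A35	A39	0.256743	1.35968	0.641667
A36	A39	0.29676	1.21483	0.966667
A38	A39	0.223812	1.49695	0.933333
A39	A40	-0.243699	1.41182	0.783333
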