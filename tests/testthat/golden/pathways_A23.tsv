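target	found	cost	path
A23	TRUE	0	A23
A24	TRUE	0.725028	A23-A24
A25	TRUE	1.56748	A23-A24-A25
A26	TRUE	1.9639	A23-A38-A37-A34-A26
A27	TRUE	1.26865	A23-A24-A27
A28	TRUE	1.79399	A23-A24-A27-A28
A33	TRUE	1.80131	A23-A38-A37-A34-A33
A34	TRUE	1.40067	A23-A38-A37-A34
A35	TRUE	1.72542	A23-A38-A37-A34-A35
A36	TRUE	1.48419	A23-A38-A37-A36
A37	TRUE	1.033	A23-A38-A37
A38	TRUE	0.657129	A23-A38
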