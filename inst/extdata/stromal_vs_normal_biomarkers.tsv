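gene	avg_log2fc	pct_in	pct_out	p_adj
COL1A2	3.416	0.746	0.139	2.8E-84
COL3A1	3.093	0.702	0.097	1.88E-77
COL1A1	3.481	0.733	0.231	1.17E-71
COL6A3	1.985	0.567	0.083	1.09E-50
COL5A1	1.825	0.509	0.05	7.49E-46
COL5A2	1.634	0.488	0.028	4.77E-45
COL4A1	2.313	0.542	0.094	4.18E-42
COL4A2	1.871	0.554	0.122	3.91E-39
COL6A1	1.154	0.676	0.317	4.17E-30
MMP2	1.152	0.377	0.047	1.27E-26
TIMP1	1.457	0.718	0.425	2.08E-25
MMP11	1.185	0.189	0.008	1.03E-12
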