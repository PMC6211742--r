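gene	avg_log2fc	pct_in	pct_out	p_adj
WFDC2	2.373	0.772	0.108	0
CLDN4	2.271	0.615	0.034	0
FXYD3	2.202	0.537	0.025	0
CD24	2.111	0.647	0.071	0
ELF3	2.061	0.636	0.061	0
CLDN3	2.045	0.623	0.031	0
MUC1	1.995	0.648	0.08	0
SPINT2	1.831	0.638	0.09	0
KRT8	1.767	0.664	0.086	0
SLPI	1.681	0.646	0.074	0
KRT18	1.640	0.671	0.134	0
KRT19	1.590	0.613	0.098	4.7E-297
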