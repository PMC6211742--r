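cluster	gene	avg_log2fc	pct_in	pct_out	p_adj
HGSOC-F epithelial	TPPP3	3.377	0.885	0.083	1.1E-279
HGSOC-F epithelial	C20orf85	3.177	0.723	0.007	4.8E-299
HGSOC-F epithelial	FOXJ1	2.545	0.857	0.257	6E-159
HGSOC-F epithelial	RSPH1	2.455	0.615	0.033	1.2E-199
HGSOC-F epithelial	ZMYND10	2.285	0.569	0.02	4.7E-198
HGSOC-F epithelial	CAPS	2.197	0.731	0.218	2.3E-118
HG3 tumor epithelial	SST	3.771	0.547	0.022	4.6E-181
HG3 tumor epithelial	TFF3	2.665	0.607	0.054	1.4E-176
HG3 tumor epithelial	PIGR	2.628	0.661	0.017	7.3E-243
HG3 tumor epithelial	GPNMB	2.010	0.65	0.021	4.7E-227
HG3 tumor epithelial	XBP1	1.824	0.768	0.173	6E-179
HG3 tumor epithelial	LYNX1	1.792	0.553	0.034	1.7E-169
HG3 tumor epithelial	AGR2	1.727	0.603	0.055	2.5E-170
HG3 tumor epithelial	DDIT4	1.639	0.846	0.272	2E-162
HG3 tumor epithelial	CXCL17	1.575	0.608	0.055	2.6E-173
HG3 tumor epithelial	KIAA1324	1.564	0.561	0.025	1.2E-180
HG3 tumor epithelial	NNMT	1.522	0.654	0.085	1.1E-164
HG3 tumor epithelial	STARD10	1.392	0.585	0.079	6.5E-142
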