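group	differentiated	immunoreactive	mesenchymal	proliferative
BN1-P	3.246	0.712	1.062	0.189
HG1-P	1.144	0.613	1.476	0.544
HG1-M	1.113	0.887	2.299	0.347
HG2F-P	1.942	0.240	0.657	0.608
HG2F-M	1.351	1.231	0.574	0.345
HG3-P	2.062	1.037	1.426	0.464
HG3-M	1.498	1.681	0.956	0.350
HG4-P	1.523	2.527	0.732	0.366
HG4-M	1.934	0.228	0.834	0.292
LG1-P	0.999	0.590	1.902	0.395
LG1-N	0.871	0.124	1.973	0.416
LG2-P	3.604	0.514	1.449	0.284
LG2-M	2.968	0.684	3.831	0.236
PN1-P	1.594	0.291	1.635	0.690
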