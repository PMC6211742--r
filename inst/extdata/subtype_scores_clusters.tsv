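group	differentiated	immunoreactive	mesenchymal	proliferative
B-cells	0.194	1.496	0.318	0.442
benign epithelial	4.216	0.621	0.654	0.180
cancer stromal cells	0.447	0.142	4.559	0.355
CD4 T-cells	1.848	1.245	0.353	0.331
CD8 T-cells	1.105	1.594	0.568	0.349
endothelial progenitor	1.112	0.208	2.012	0.481
HGSOC-F tumor epithelial	2.946	0.202	0.347	0.424
LGSOC epithelial	3.808	0.227	0.488	0.304
metastatic fibroblasts	1.304	0.270	5.074	0.389
metastatic myeloid lineage	1.129	3.931	1.088	0.261
normal fibroblasts	0.553	0.159	1.429	0.616
normal stromal cells	0.937	0.076	2.439	0.293
HGSOC epithelial	1.691	0.226	0.413	0.569
primary fibroblasts	0.493	0.174	3.337	0.582
primary myeloid lineage	0.744	3.732	1.354	0.272
HG3 tumor epithelial	2.753	0.822	0.711	0.491
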