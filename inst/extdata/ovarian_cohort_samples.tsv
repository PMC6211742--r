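patient_id	age	neoplasm	stage	prev_breast_cancer	neoadjuvant	race	sample_id	site	n_cells
BN1	56	benign	NA	no	no	White	BN1-P	primary	223
HG1	70	HGSOC	IIIA	NA	no	not reported	HG1-P	primary	252
HG1	70	HGSOC	IIIA	NA	no	not reported	HG1-M	metastatic	325
HG2F	67	HGSOC-F	IIIB	no	no	not reported	HG2F-P	primary	260
HG2F	67	HGSOC-F	IIIB	no	no	not reported	HG2F-M	metastatic	259
HG3	66	HGSOC	IIIC	yes	no	White	HG3-P	primary	213
HG3	66	HGSOC	IIIC	yes	no	White	HG3-M	metastatic	312
HG4	54	HGSOC	IIIA	no	no	More than one race	HG4-P	primary	174
HG5	69	HGSOC	IIIC	yes	yes	Black or African American	HG5-P	primary	56
LG1	67	LGSOC	IA	no	no	White	LG1-P	primary	194
LG1	67	LGSOC	IA	no	no	White	NM1	normal	344
LG2	58	LGSOC	IIIC	no	no	Asian	LG2-P	primary	130
LG2	58	LGSOC	IIIC	no	no	Asian	LG2-M	metastatic	125
PN1	55	peritoneal	IV	no	no	White	PN1-P	primary	44
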