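variant_id	cdna	SIFT_verdict	PolyPhen2_verdict	LRT_verdict	MutationTaster_verdict	MutationAssessor_verdict	PROVEAN_verdict	MetaSVM_verdict	M-CAP_verdict	Revel_verdict	MutPred_verdict	MVP_verdict	DEOGEN2_verdict	ClinPred_verdict	LIST-S2_verdict	CADD_verdict	SIFT_score	PolyPhen2_score	LRT_score	MutationTaster_score	MutationAssessor_score	PROVEAN_score	MetaSVM_score	M-CAP_score	Revel_score	MutPred_score	MVP_score	DEOGEN2_score	ClinPred_score	LIST-S2_score	CADD_score
Q100H	c.300G>T	B	B	B	P	P	B	P	P	P	B	P	B	P	P	B	0.75	0.60	0.30	0.81	0.54	0.56	0.84	0.59	0.71	0.52	0.93	0.53	0.38	0.71	0.60
T168I	c.503C>T	P	P	P	P	P	P	P	P	P	P	P	P	P	P	P	0.78	0.92	0.84	0.81	0.90	0.86	0.98	0.89	0.99	0.87	0.98	0.94	0.85	0.74	0.71
H282D	c.844C>G	P	P	P	P	P	P	P	P	P	P	P	B	P	P	P	0.78	0.75	0.84	0.81	0.85	0.98	0.87	0.75	0.96	0.96	0.98	0.78	0.95	0.73	0.85
H345Y	c.1033C>T	P	P	P	P	P	P	P	P	P	P	P	B	P	P	P	0.91	0.97	0.84	0.81	0.86	0.87	0.91	0.83	0.98	0.99	0.97	0.74	0.89	0.98	0.84
A392V	c.1175C>T	P	P	P	P	P	P	P	P	P	NA	B	P	P	P	P	0.91	0.78	0.84	0.81	0.95	0.72	0.93	0.88	0.95	NA	0.72	0.82	0.75	0.96	0.83
P471L	c.1412C>T	P	P	P	P	P	P	P	P	P	P	B	B	P	P	P	0.78	0.84	0.84	0.81	0.90	0.97	0.90	0.78	0.82	0.89	0.73	0.75	0.88	0.91	0.83
R474C	c.1420C>T	P	P	P	P	P	P	P	P	P	P	P	P	P	P	P	0.91	0.97	0.84	0.81	1.00	0.95	0.96	0.82	0.97	1.00	0.95	0.83	0.98	0.94	0.80
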