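snp_id	chrom	gene	effect_allele	eaf	beta_exposure	se_exposure	p_exposure	beta_outcome	se_outcome	p_outcome	mapped_phenotypes
rs140394939	1	PDE4B	A	0.015	-0.098	0.020	1.20e-06	-0.117	0.380	0.758	Vitamin C intake;Carotene intake
rs16846116	2	LRP1B	A	0.070	0.044	0.009	1.20e-06	0.129	0.159	0.416	Vitamin C intake;Weight;BMI
rs147902155	8	SNAI2	A	0.029	-0.068	0.014	2.00e-06	-0.308	0.306	0.315	Vitamin C intake;Potassium intake;Vitamin B2 intake
rs12031723	1	PTBP2	C	0.250	-0.026	0.006	2.90e-06	-0.129	0.101	0.201	Vitamin C intake;Fiber intake;Potassium intake
rs76463900	5	HDAC3	A	0.140	0.032	0.007	4.60e-06	-0.041	0.120	0.734	Vitamin C intake;WBC;Height
rs10074128	5	PRLR	G	0.390	0.022	0.005	6.90e-06	0.067	0.083	0.415	Vitamin C intake;Vitamin A intake;Folate intake;BUN
rs2521745	7	NPVF	A	0.800	0.026	0.006	7.30e-06	0.036	0.131	0.785	Vitamin C intake;Fiber intake;Vitamin B6 intake;Carotene intake
rs3828277	2	TNS1	T	0.065	-0.042	0.009	7.50e-06	-0.101	0.153	0.508	Vitamin C intake;Potassium intake;HbA1c
rs146782291	8	C8orf37	A	0.044	0.052	0.012	8.90e-06	0.203	0.256	0.427	Vitamin C intake;Fiber intake;Colorectal cancer
rs898833	1	STUM	T	0.230	-0.024	0.006	9.40e-06	-0.083	0.100	0.406	Vitamin C intake;Vitamin B6 intake;Fiber intake
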