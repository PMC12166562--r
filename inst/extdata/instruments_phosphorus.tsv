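snp_id	chrom	gene	effect_allele	eaf	beta_exposure	se_exposure	p_exposure	beta_outcome	se_outcome	p_outcome	mapped_phenotypes
rs8074317	17	SEPTIN9	T	0.220	-0.021	0.0036	6.00e-09	-0.024	0.099	0.806	Phosphorus intake;Vitamin B2 intake
rs138424249	14	LRFN5	A	0.092	0.029	0.0054	6.20e-08	-0.179	0.145	0.218	Phosphorus intake
rs930110	7	FZD1	G	0.530	0.015	0.0030	2.50e-07	0.019	0.103	0.850	Phosphorus intake
rs10193255	2	RBM43	C	0.330	-0.016	0.0032	4.20e-07	0.032	0.084	0.700	Phosphorus intake
rs77133047	8	DOK2	T	0.180	-0.019	0.0039	1.10e-06	-0.153	0.129	0.234	Phosphorus intake
rs7126868	11	PRMT3	C	0.340	0.015	0.0032	1.50e-06	0.014	0.101	0.889	Phosphorus intake
rs78281436	18	MYO5B	C	0.046	-0.036	0.0075	1.50e-06	0.202	0.215	0.347	Phosphorus intake;HDL
rs145817449	5	MROH2B	C	0.018	-0.053	0.0110	2.70e-06	-0.307	0.280	0.272	Phosphorus intake;Gastric cancer
rs365215	11	PLEKHA7	C	0.280	0.016	0.0034	3.30e-06	0.090	0.104	0.385	Phosphorus intake;BMI
rs2567388	4	EMCN	T	0.300	-0.015	0.0033	4.70e-06	-0.067	0.084	0.427	Phosphorus intake;Hyperlipidemia
rs7902081	10	HMX3	C	0.130	-0.022	0.0049	5.40e-06	-0.070	0.131	0.595	Phosphorus intake
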