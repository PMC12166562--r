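snp_id	chrom	gene	effect_allele	eaf	beta_exposure	se_exposure	p_exposure	beta_outcome	se_outcome	p_outcome	mapped_phenotypes
rs145928548	3	NSUN3	T	0.015	-0.072	0.014	9.20e-08	0.319	0.351	0.363	Vitamin B6 intake
rs184559817	5	HMHB1	A	0.010	0.088	0.017	1.50e-07	-0.421	0.472	0.372	Vitamin B6 intake;Height
rs148237512	3	NSUN3	T	0.015	-0.069	0.014	5.30e-07	0.450	0.369	0.223	Vitamin B6 intake
rs77055181	19	NPHS1	A	0.086	-0.029	0.006	7.10e-07	0.027	0.160	0.867	Vitamin B6 intake;Iron intake;Creatinine
rs4742795	9	CAVIN4	A	0.380	0.017	0.004	8.90e-07	-0.091	0.084	0.279	Vitamin B6 intake;Niacin intake
rs141302176	10	ADAM12	A	0.026	-0.048	0.010	2.10e-06	0.169	0.243	0.486	Vitamin B6 intake;Niacin intake;Iron intake
rs2071987	1	VAMP3	A	0.390	0.015	0.003	5.60e-06	-0.043	0.087	0.623	Vitamin B6 intake;Iron intake;Folate intake
rs375382680	1	ATP2B4	T	0.020	-0.052	0.012	7.40e-06	-0.099	0.294	0.737	Vitamin B6 intake;Fiber intake;Iron intake
rs12192239	6	DLL1	T	0.630	-0.016	0.004	7.90e-06	0.195	0.097	0.045	Vitamin B6 intake;Iron intake;Folate intake
rs35280662	2	AC007040.2	A	0.035	-0.042	0.009	8.10e-06	0.217	0.229	0.344	Vitamin B6 intake;Ash intake;Sodium intake
rs9289799	3	PFN2	G	0.200	0.018	0.004	9.50e-06	-0.015	0.099	0.883	Vitamin B6 intake;Iron intake;Niacin intake
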