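snp_id	chrom	gene	effect_allele	eaf	beta_exposure	se_exposure	p_exposure	beta_outcome	se_outcome	p_outcome	mapped_phenotypes
rs8074201	17	SEPTIN9	T	0.220	-0.024	0.004	3.90e-08	-0.024	0.099	0.804	Vitamin B2 intake;Phosphorus intake
rs147957210	1	PRKCZ	G	0.032	-0.048	0.010	1.60e-06	-0.349	0.239	0.144	Vitamin B2 intake;BMI
rs141095648	13	NUFIP1	A	0.075	-0.032	0.007	2.80e-06	0.004	0.156	0.980	Vitamin B2 intake;Sodium intake
rs17018468	3	LRRC3B	G	0.290	-0.018	0.004	3.20e-06	-0.037	0.087	0.667	Vitamin B2 intake;Iron intake;Calcium intake
rs1974852	5	EMB	A	0.170	-0.023	0.005	3.40e-06	0.008	0.110	0.940	Vitamin B2 intake;DM
rs80277692	3	NMD3	G	0.140	-0.024	0.005	3.60e-06	-0.104	0.117	0.373	Vitamin B2 intake;Gastric cancer
rs1485984	2	KCNH7	T	0.380	0.017	0.004	4.20e-06	0.074	0.082	0.368	Vitamin B2 intake;Creatinine
rs72822548	10	SORBS1	A	0.370	-0.017	0.004	4.30e-06	-0.116	0.085	0.174	Vitamin B2 intake;RBC
rs10193255	2	RBM43	C	0.330	-0.017	0.004	6.40e-06	0.032	0.084	0.700	Vitamin B2 intake;Phosphorus intake
rs1346667	7	FZD1	G	0.200	0.020	0.005	7.20e-06	0.029	0.128	0.820	Vitamin B2 intake;Phosphorus intake;Calcium intake
rs10973705	9	SHB	T	0.470	-0.016	0.004	8.70e-06	-0.133	0.081	0.100	Vitamin B2 intake;Calcium intake
rs185500746	4	FBXW7	C	0.024	-0.051	0.011	8.70e-06	-0.080	0.253	0.750	Vitamin B2 intake;DM
rs146438270	6	LRFN2	T	0.020	-0.061	0.014	9.60e-06	0.038	0.358	0.915	Vitamin B2 intake;BMI
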