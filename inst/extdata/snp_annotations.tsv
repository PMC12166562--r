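snp_id	mapped_phenotypes
rs10074128	BUN;Folate intake;Vitamin A intake;Vitamin C intake
rs10193255	Phosphorus intake;Vitamin B2 intake
rs10973705	Calcium intake;Vitamin B2 intake
rs12031723	Fiber intake;Potassium intake;Vitamin C intake
rs12192239	Folate intake;Iron intake;Vitamin B6 intake
rs1346667	Calcium intake;Phosphorus intake;Vitamin B2 intake
rs138424249	Phosphorus intake
rs140394939	Carotene intake;Vitamin C intake
rs141095648	Sodium intake;Vitamin B2 intake
rs141302176	Iron intake;Niacin intake;Vitamin B6 intake
rs145817449	Gastric cancer;Phosphorus intake
rs145928548	Vitamin B6 intake
rs146438270	BMI;Vitamin B2 intake
rs146782291	Colorectal cancer;Fiber intake;Vitamin C intake
rs147902155	Potassium intake;Vitamin B2 intake;Vitamin C intake
rs147957210	BMI;Vitamin B2 intake
rs148237512	Vitamin B6 intake
rs1485984	Creatinine;Vitamin B2 intake
rs16846116	BMI;Vitamin C intake;Weight
rs17018468	Calcium intake;Iron intake;Vitamin B2 intake
rs184559817	Height;Vitamin B6 intake
rs185500746	DM;Vitamin B2 intake
rs1974852	DM;Vitamin B2 intake
rs2071987	Folate intake;Iron intake;Vitamin B6 intake
rs2521745	Carotene intake;Fiber intake;Vitamin B6 intake;Vitamin C intake
rs2567388	Hyperlipidemia;Phosphorus intake
rs35280662	Ash intake;Sodium intake;Vitamin B6 intake
rs365215	BMI;Phosphorus intake
rs375382680	Fiber intake;Iron intake;Vitamin B6 intake
rs3828277	HbA1c;Potassium intake;Vitamin C intake
rs4742795	Niacin intake;Vitamin B6 intake
rs7126868	Phosphorus intake
rs72822548	RBC;Vitamin B2 intake
rs76463900	Height;Vitamin C intake;WBC
rs77055181	Creatinine;Iron intake;Vitamin B6 intake
rs77133047	Phosphorus intake
rs78281436	HDL;Phosphorus intake
rs7902081	Phosphorus intake
rs80277692	Gastric cancer;Vitamin B2 intake
rs8074201	Phosphorus intake;Vitamin B2 intake
rs8074317	Phosphorus intake;Vitamin B2 intake
rs898833	Fiber intake;Vitamin B6 intake;Vitamin C intake
rs9289799	Iron intake;Niacin intake;Vitamin B6 intake
rs930110	Phosphorus intake
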