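nutrient	quantity	reference	tolerance
phosphorus	ivw_beta	1.110	0.05
phosphorus	ivw_se	1.728	0.05
vitamin_b2	ivw_beta	2.637	0.05
vitamin_b2	ivw_se	1.376	0.05
vitamin_b6	ivw_beta	-4.014	0.05
vitamin_b6	ivw_se	1.624	0.05
vitamin_c	ivw_beta	2.572	0.05
vitamin_c	ivw_se	1.275	0.05
vitamin_b6	radial_beta	-4.016	0.05
vitamin_c	radial_beta	2.573	0.05
vitamin_b6	simple_median_beta	-4.431	0.01
vitamin_b6	egger_intercept	-0.026	0.005
phosphorus	egger_intercept	0.059	0.01
vitamin_b2	egger_intercept	0.044	0.005
vitamin_c	egger_intercept	0.016	0.005
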