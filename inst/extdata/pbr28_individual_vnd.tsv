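subject	sime_vnd	lassen_2tcm_vnd	lassen_2tcm_ci_lo	lassen_2tcm_ci_hi	rel_diff_pct_printed	lassen_2tcm1k_vnd	lassen_2tcm1k_ci_lo	lassen_2tcm1k_ci_hi
#305	1.24	5.55	4.46	6.43	-78	0.14	0.11	0.16
#314	0.94	3.05	2.45	3.53	-69	0.78	0.63	0.91
#316	1.68	2.31	1.86	2.67	-27	1.03	0.83	1.19
#337	1.14	1.51	1.17	1.78	-24	0.27	0.21	0.32
#338	1.17	2.09	1.68	2.41	-44	1.01	0.81	1.16
#339	0.71	1.67	1.34	1.94	-58	0.89	0.71	1.03
#378	1.24	1.50	1.20	1.73	-17	0.75	0.60	0.86
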