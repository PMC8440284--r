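region	model	vt_baseline_mean	vt_baseline_sd	vt_block_mean	vt_block_sd	vt_change_pct_printed
whole_brain	2tcm	4.72	1.18	2.16	1.05	54
white_matter	2tcm	4.30	0.95	1.97	0.58	54
gray_matter	2tcm	4.95	1.26	2.45	1.62	50
occipital_lobe	2tcm	4.76	1.26	2.91	2.36	39
temporal_lobe	2tcm	4.82	1.16	2.06	0.85	57
frontal_lobe	2tcm	4.81	1.21	2.43	1.57	49
parietal_lobe	2tcm	4.64	1.18	2.91	2.65	37
amygdala	2tcm	6.67	2.09	1.62	0.53	76
hippocampus	2tcm	5.25	1.23	1.88	0.51	64
thalamus	2tcm	5.70	1.28	1.79	0.45	69
striatum	2tcm	4.83	1.01	1.86	0.60	61
cerebellum	2tcm	4.87	1.25	2.27	1.44	53
whole_brain	2tcm1k	2.31	0.63	0.70	0.26	70
white_matter	2tcm1k	1.34	0.38	0.62	0.10	54
gray_matter	2tcm1k	2.64	0.71	0.76	0.34	71
occipital_lobe	2tcm1k	2.56	0.73	0.70	0.31	73
temporal_lobe	2tcm1k	2.43	0.75	0.73	0.29	70
frontal_lobe	2tcm1k	2.49	0.65	0.73	0.30	71
parietal_lobe	2tcm1k	2.42	0.67	0.71	0.31	71
amygdala	2tcm1k	2.49	1.55	1.14	0.22	54
hippocampus	2tcm1k	2.59	1.07	1.04	0.35	60
thalamus	2tcm1k	2.45	0.78	0.90	0.29	63
striatum	2tcm1k	2.62	1.03	0.74	0.18	72
cerebellum	2tcm1k	2.71	0.65	0.78	0.34	71
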