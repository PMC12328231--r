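ligand	population	log2fc	log2fc_capped	p	padj	pct_in	pct_out
CDO1	MSC	6.989	5	9.4e-05	0.00376	0.743	0.077
APOE	osteo	7.122	5	9.78e-05	0.00391	0.787	0.071
KITLG	arteriolar_EC	3.217	3.217	1.18e-05	0.000472	0.533	0.051
THBS1	sinusoidal_EC	6.483	5	4.75e-05	0.0019	0.711	0.078
L_SURF01	MSC	5.35	5	5.6e-05	0.00224	0.302	0.05
L_SURF02	osteo	4.615	4.615	9.04e-05	0.00362	0.8	0.027
L_SURF03	arteriolar_EC	5.92	5	1.39e-05	0.000556	0.304	0.028
L_PRKD2	sinusoidal_EC	2.308	2.308	9.89e-05	0.00396	0.425	0.032
L_CD33	MSC	5.442	5	9.47e-05	0.00379	0.844	0.063
L_SURF04	osteo	5.73	5	8.25e-06	0.00033	0.667	0.003
L_SURF05	arteriolar_EC	4.246	4.246	5.14e-05	0.00206	0.528	0.06
L_SURF06	sinusoidal_EC	5.815	5	3.9e-05	0.00156	0.561	0.054
L_SURF07	MSC	7.108	5	9.06e-05	0.00362	0.322	0.014
L_SURF08	osteo	3.033	3.033	4.47e-05	0.00179	0.884	0.021
L_SURF09	arteriolar_EC	4.274	4.274	8.36e-05	0.00334	0.559	0.041
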