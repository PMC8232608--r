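oxygen_pct	condition	theta	kappa	j	f_R_default	nuclear_diameter_um	genome_gbp
21	aerobic	5.79e-3	5.59e-5	9	0.99	8	6
2	moderate_hypoxia	5.79e-3	5.59e-5	8	0.99	8	6
0.1	severe_hypoxia	4.1e-3	3e-5	7	0.98	8	6
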