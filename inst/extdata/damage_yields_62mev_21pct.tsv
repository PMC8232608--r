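position	oxygen_pct	BD	SSB	SSBp	SSB2	DSB	DSBp	DSBpp	total_SSB	total_SSB_sd	total_DSB	total_DSB_sd	total_damage	total_damage_sd
P1	21	421	178	8.07	1.01	7.19	0.990	0.117	187	0.0246	8.28	0.0109	616	0.0461
P2	21	405	174	8.80	1.20	7.62	1.15	0.154	184	0.0254	8.93	0.0112	599	0.0506
P3	21	394	171	9.72	1.48	7.86	1.36	0.213	183	0.0325	9.43	0.0124	585	0.136
P4	21	367	163	12.3	2.44	8.19	1.94	0.474	178	0.0745	10.6	0.0204	556	0.413
P5	21	354	159	13.2	2.81	8.44	2.19	0.588	175	0.0870	11.2	0.0229	540	0.475
P6	21	328	154	13.9	3.08	9.21	2.52	0.668	170	0.0814	12.4	0.0221	511	0.447
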