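position	oxygen_pct	dsb_yield	dsb_yield_sd	rbe_printed	rbe_printed_sd
P1	21	8.28	0.0109	1.02	0.00186
P2	21	8.93	0.0112	1.10	0.00182
P3	21	9.43	0.0124	1.16	0.00186
P4	21	10.6	0.0204	1.30	0.00233
P5	21	11.2	0.0229	1.38	0.00243
P6	21	12.4	0.0221	1.52	0.00221
Co60	21	8.14	0.0107	NA	NA
P1	2	6.97	0.00997	1.02	0.00203
P2	2	7.52	0.0103	1.10	0.00199
P3	2	7.95	0.0114	1.16	0.00203
P4	2	9.00	0.0188	1.31	0.00254
P5	2	9.54	0.0214	1.39	0.00267
P6	2	10.6	0.0204	1.55	0.00241
Co60	2	6.85	0.00988	NA	NA
P1	0.1	3.54	0.00735	1.02	0.00293
P2	0.1	3.82	0.00765	1.10	0.00288
P3	0.1	4.05	0.00817	1.17	0.00289
P4	0.1	4.68	0.0131	1.35	0.00348
P5	0.1	5.03	0.0152	1.45	0.00366
P6	0.1	5.65	0.0141	1.62	0.00325
Co60	0.1	3.48	0.00720	NA	NA
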