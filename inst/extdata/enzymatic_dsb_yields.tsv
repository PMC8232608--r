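position	dsb_induction	max_conversion	rbe_dsb_printed	rbe_conversion_printed
P1	8.28	5.72	1.02	0.95
P2	8.93	6.19	1.10	1.03
P3	9.43	6.73	1.16	1.12
P4	10.6	8.77	1.31	1.46
P5	11.2	9.43	1.38	1.57
P6	12.4	9.66	1.53	1.61
Co60	8.14	6.00	NA	NA
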