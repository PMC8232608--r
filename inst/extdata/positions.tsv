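position	depth_descriptor	let_kev_um	beam_energy_mev
P1	entrance plateau	1.11	62
P2	plateau	4.02	62
P3	proximal rise	7.00	62
P4	Bragg peak proximal	11.9	62
P5	Bragg peak	18.0	62
P6	Bragg peak distal	22.6	62
Co60	reference gamma	2.40	NA
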