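pathway	position	p_correct	p_mutation	p_dsb
LP_BER	P1	0.962	0.029	0.009
LP_BER	P2	0.958	0.032	0.010
LP_BER	P3	0.954	0.035	0.011
LP_BER	P4	0.938	0.046	0.016
LP_BER	P5	0.932	0.051	0.017
LP_BER	P6	0.926	0.055	0.019
SP_BER	P1	0.983	0.008	0.008
SP_BER	P6	0.967	0.017	0.016
SP_BER_NER	P1	0.899	0.062	0.038
SP_BER_NER	P6	0.822	0.106	0.072
LP_BER_NER	P1	0.896	0.065	0.038
LP_BER_NER	P6	0.818	0.110	0.072
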