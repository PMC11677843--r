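group	category	n	vus_n
FH_PLP	ldl_only	9	0
FH_PLP	lpa_only	4	0
FH_PLP	both	0	0
FH_PLP	none	60	3
PHENOCOPY_PLP	ldl_only	1	0
PHENOCOPY_PLP	lpa_only	1	0
PHENOCOPY_PLP	both	0	0
PHENOCOPY_PLP	none	5	0
NON_FH	ldl_only	45	2
NON_FH	lpa_only	16	0
NON_FH	both	7	0
NON_FH	none	191	12
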