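d_gene	high_exo	normal_exo
IGHDS1	1	3
IGHDS2	31	10
IGHDS3	7	85
IGHDS4	0	24
IGHDS5	14	254
IGHDS6	0	1
IGHDS7	0	79
IGHDS8	0	71
IGHDS9	0	9
IGHDS10	0	3
IGHDS11	5	4
IGHDS12	2	7
IGHDS13	0	3
IGHDS14	3	29
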