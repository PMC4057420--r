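v_gene	j_gene	count
IGLV30	IGLJ3	20
IGLV30	IGLJ2	3
IGLV39	IGLJ3	7
IGLV39	IGLJ2	1
IGLV49	IGLJ3	7
IGLV8	IGLJ3	6
IGLV8	IGLJ2	1
IGLV43	IGLJ3	4
IGLV28	IGLJ3	4
IGLV25	IGLJ3	3
IGLV55	IGLJ3	2
IGLV35	IGLJ3	2
IGLV2	IGLJ3	2
IGLV6	IGLJ3	2
IGLV56	IGLJ2	1
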