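v_gene	d_gene	j_gene	count
IGHV1S1	IGHDS12	JH1	5
IGHV1S1	IGHDS14	JH1	17
IGHV1S1	IGHDS2	JH1	2
IGHV1S1	IGHDS2	JH6	1
IGHV1S1	IGHDS3	JH1	3
IGHV1S1	IGHDS3	JH6	1
IGHV1S1	IGHDS5	JH1	14
IGHV1S1	IGHDS7	JH1	3
IGHV1S1	IGHDS8	JH1	2
IGHV1S1	IGHDS8	JH6	9
IGHV1S10	IGHDS12	JH1	1
IGHV1S10	IGHDS2	JH1	1
IGHV1S10	IGHDS3	JH1	2
IGHV1S10	IGHDS5	JH1	8
IGHV1S10	IGHDS7	JH1	3
IGHV1S11	IGHDS10	JH1	1
IGHV1S11	IGHDS14	JH1	3
IGHV1S11	IGHDS3	JH1	3
IGHV1S11	IGHDS3	JH6	2
IGHV1S11	IGHDS5	JH1	6
IGHV1S11	IGHDS7	JH1	4
IGHV1S11	IGHDS8	JH6	1
IGHV1S14	IGHDS14	JH1	1
IGHV1S14	IGHDS2	JH1	1
IGHV1S14	IGHDS3	JH1	1
IGHV1S14	IGHDS4	JH1	1
IGHV1S14	IGHDS5	JH1	2
IGHV1S14	IGHDS7	JH1	5
IGHV1S14	IGHDS8	JH1	2
IGHV1S14	IGHDS8	JH6	3
IGHV1S14	IGHDS9	JH1	1
IGHV1S15	IGHDS1	JH1	1
IGHV1S15	IGHDS10	JH1	1
IGHV1S15	IGHDS11	JH1	1
IGHV1S15	IGHDS13	JH1	3
IGHV1S15	IGHDS2	JH1	13
IGHV1S15	IGHDS3	JH1	32
IGHV1S15	IGHDS4	JH1	7
IGHV1S15	IGHDS5	JH1	25
IGHV1S15	IGHDS7	JH1	5
IGHV1S15	IGHDS8	JH1	9
IGHV1S15	IGHDS9	JH1	2
IGHV1S16	IGHDS5	JH1	4
IGHV1S16	IGHDS7	JH1	1
IGHV1S18	IGHDS3	JH1	4
IGHV1S18	IGHDS5	JH1	15
IGHV1S18	IGHDS7	JH1	2
IGHV1S19	IGHDS7	JH1	1
IGHV1S2	IGHDS3	JH1	1
IGHV1S2	IGHDS5	JH1	2
IGHV1S2	IGHDS8	JH6	2
IGHV1S24	IGHDS5	JH2	1
IGHV1S24	IGHDS9	JH1	4
IGHV1S26	IGHDS4	JH1	1
IGHV1S26	IGHDS8	JH6	1
IGHV1S27	IGHDS8	JH1	1
IGHV1S28	IGHDS12	JH1	1
IGHV1S28	IGHDS14	JH1	2
IGHV1S28	IGHDS2	JH1	10
IGHV1S28	IGHDS3	JH1	8
IGHV1S28	IGHDS4	JH1	3
IGHV1S28	IGHDS5	JH1	27
IGHV1S28	IGHDS7	JH1	10
IGHV1S28	IGHDS8	JH1	2
IGHV1S28	IGHDS9	JH6	1
IGHV1S29	IGHDS5	JH1	1
IGHV1S29	IGHDS7	JH1	1
IGHV1S3	IGHDS1	JH1	3
IGHV1S3	IGHDS10	JH1	1
IGHV1S3	IGHDS11	JH1	4
IGHV1S3	IGHDS14	JH1	8
IGHV1S3	IGHDS2	JH1	3
IGHV1S3	IGHDS2	JH6	5
IGHV1S3	IGHDS3	JH1	19
IGHV1S3	IGHDS4	JH1	11
IGHV1S3	IGHDS5	JH1	31
IGHV1S3	IGHDS5	JH6	2
IGHV1S3	IGHDS6	JH1	1
IGHV1S3	IGHDS7	JH1	24
IGHV1S3	IGHDS7	JH6	1
IGHV1S3	IGHDS8	JH1	16
IGHV1S3	IGHDS8	JH6	13
IGHV1S3	IGHDS9	JH1	1
IGHV1S31	IGHDS11	JH1	1
IGHV1S31	IGHDS3	JH1	1
IGHV1S31	IGHDS5	JH1	9
IGHV1S33	IGHDS11	JH1	1
IGHV1S33	IGHDS3	JH1	1
IGHV1S33	IGHDS5	JH1	6
IGHV1S33	IGHDS7	JH1	4
IGHV1S33	IGHDS8	JH1	1
IGHV1S34	IGHDS12	JH1	1
IGHV1S34	IGHDS2	JH1	1
IGHV1S34	IGHDS3	JH1	6
IGHV1S34	IGHDS5	JH1	11
IGHV1S34	IGHDS7	JH1	1
IGHV1S34	IGHDS8	JH1	1
IGHV1S35	IGHDS2	JH1	1
IGHV1S35	IGHDS5	JH1	1
IGHV1S35	IGHDS7	JH1	1
IGHV1S36	IGHDS3	JH1	1
IGHV1S38	IGHDS8	JH6	1
IGHV1S39	IGHDS11	JH1	2
IGHV1S39	IGHDS12	JH1	1
IGHV1S39	IGHDS14	JH1	1
IGHV1S39	IGHDS2	JH1	1
IGHV1S39	IGHDS3	JH1	2
IGHV1S39	IGHDS5	JH1	84
IGHV1S39	IGHDS7	JH1	8
IGHV1S39	IGHDS7	JH6	1
IGHV1S39	IGHDS8	JH6	3
IGHV1S4	IGHDS3	JH1	1
IGHV1S4	IGHDS8	JH6	3
IGHV1S40	IGHDS2	JH1	2
IGHV1S40	IGHDS5	JH1	3
IGHV1S6	IGHDS3	JH1	3
IGHV1S6	IGHDS4	JH1	1
IGHV1S6	IGHDS5	JH1	15
IGHV1S6	IGHDS7	JH1	4
IGHV1S7	IGHDS3	JH1	1
IGHV1S7	IGHDS5	JH1	1
IGHV1S7	IGHDS8	JH1	1
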