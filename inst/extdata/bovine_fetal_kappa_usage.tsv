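v_gene	j_gene	count
IGKV19	IGKJ1	53
IGKV10	IGKJ1	28
IGKV10	IGKJ2	1
IGKV17	IGKJ1	1
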