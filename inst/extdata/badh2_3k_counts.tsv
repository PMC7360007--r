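hap_group	aus	indica	admix	aromatic	temperate japonica	tropical japonica	japonica admixture
Hap1	1	749	12	0	1	121	8
Hap2	2	148	19	26	215	281	64
Hap3	0	201	1	0	1	0	0
Hap4	9	183	5	0	0	0	0
Hap5	1	186	5	2	0	1	0
Hap6	0	65	9	38	3	53	3
Hap7	97	11	6	0	0	0	0
Hap8	0	89	2	1	0	2	0
Hap9	63	13	6	3	0	0	0
Hap10	1	39	6	0	2	4	0
Hap11	3	22	6	0	0	0	0
R	22	42	6	2	0	2	0
U	2	41	16	3	2	3	2
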