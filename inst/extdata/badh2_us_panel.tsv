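hap	number	n_phenotyped	range_min	range_max	mean_2ap	se_2ap	aromatic	code_printed
1	181	5	0	0	0	0	FALSE	GAGGAGGT
2	134	9	0	0.079	0.009	0.005	FALSE	GTAGACCT
3	11	2	0	0	0	0	FALSE	GAGAACCT
5	5	3	0	0.001	2e-04	2e-04	FALSE	GTGGACCT
6	27	17	0.356	3.165	1.3	0.058	TRUE	TTAGACCT
7/9	11	3	0	0.009	0.003	0.002	FALSE	GAGGACCT
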