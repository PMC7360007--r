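sample	Chr8:20374951	Chr8:20380447	Chr8:20380886	Chr8:20381308	Chr8:20381787	Chr8:20382161	Chr8:20382286	Chr8:20382480	Chr8:20384350
Hap1	G	G	T	G	A	G	A	C	G
Hap2	G	C	T	G	T	A	A	C	G
Hap3	G	C	T	C	A	G	A	C	A
Hap4	G	G	T	C	A	G	A	C	G
Hap5	G	C	T	C	T	G	A	C	G
Hap6	T	C	T	C	T	A	A	C	G
Hap7	G	C	T	C	A	G	A	C	G
Hap8	G	G	T	G	A	G	G	C	G
Hap9	G	C	T	C	A	G	A	C	G
Hap10	G	G	T	G	A	G	A	T	G
Hap11	G	G	C	C	A	G	A	C	G
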