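sample_id	subpopulation
Hap1	indica
Hap2	temperate japonica
Hap3	indica
Hap4	indica
Hap5	indica
Hap6	aromatic
Hap7	aus
Hap8	indica
Hap9	aus
Hap10	indica
Hap11	indica
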