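# toy pathogenic variants on TOYB (CDS AUG GAA GAG CUG UGA)
gene_id	cds_pos	ref	alt
TOYB	4	G	T
TOYB	5	A	T
TOYB	6	A	G
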