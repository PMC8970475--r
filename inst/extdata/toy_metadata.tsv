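# toy cohort metadata; tab-separated
accession	gene_id	species	tissue	cohort	exon_count	expression_class
NM_0001	TOYA	Homo_sapiens	muscle	DC	79	high
NM_0002	TOYB	Homo_sapiens	muscle	NDC	10	medium
NM_0003	TOYC	Homo_sapiens	kidney	DC	50	low
NM_0004	TOYC	Homo_sapiens	kidney	DC	50	low
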