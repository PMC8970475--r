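>NM_0001 TOYA toy muscle gene
ATGCTGCTGTAA
>NM_0002 TOYB toy muscle gene
ATGGAAGAGCTGTGA
>NM_0003 TOYC toy kidney gene, short isoform
ATGTGCCCAAAGTAA
>NM_0004 TOYC toy kidney gene, long isoform
ATGTGCCCAAAGGGATAA
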