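symbol	chain	class	synonyms
HLA-A	alpha	1
HLA-B	alpha	1
HLA-C	alpha	1	HLA-CW
HLA-E	alpha	1
HLA-F	alpha	1
HLA-G	alpha	1
HLA-DRA	alpha	2
HLA-DRB1	beta	2
HLA-DRB3	beta	2
HLA-DRB4	beta	2
HLA-DRB5	beta	2
HLA-DQA1	alpha	2
HLA-DQA2	alpha	2
HLA-DQB1	beta	2
HLA-DQB2	beta	2
HLA-DPA1	alpha	2
HLA-DPA2	alpha	2
HLA-DPB1	beta	2
HLA-DPB2	beta	2
HLA-DMA	alpha	2
HLA-DMB	beta	2
HLA-DOA	alpha	2
HLA-DOB	beta	2
B2M	beta	1	BETA-2-MICROGLOBULIN|B2-MICROGLOBULIN
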