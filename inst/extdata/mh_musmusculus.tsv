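symbol	chain	class	synonyms
MH1-D1	alpha	1	H2-D|H2-D1|H2-DB|H2-DD|H2-DK|H2-DQ
MH1-K1	alpha	1	H2-K|H2-K1|H2-KB|H2-KD|H2-KK|H2-KQ
MH1-Q1	alpha	1	H2-Q1
MH1-Q2	alpha	1	H2-Q2
MH1-Q3	alpha	1	H2-Q3
MH1-Q4	alpha	1	H2-Q4
MH1-Q5	alpha	1	H2-Q5
MH1-Q6	alpha	1	H2-Q6
MH1-Q7	alpha	1	H2-Q7
MH1-Q8	alpha	1	H2-Q8
MH1-Q9	alpha	1	H2-Q9
MH1-Q10	alpha	1	H2-Q10
MH1-M1	alpha	1	H2-M1
MH1-M2	alpha	1	H2-M2
MH1-M3	alpha	1	H2-M3|R4B2
MH1-M4	alpha	1	H2-M4
MH1-M5	alpha	1	H2-M5|CRW2
MH1-M6	alpha	1	H2-M6
MH1-M9	alpha	1	H2-M9
MH1-M10-1	alpha	1	H2-M10.1
MH1-M10-2	alpha	1	H2-M10.2
MH1-M10-3	alpha	1	H2-M10.3
MH1-M11	alpha	1	H2-M11
MH1-T3	alpha	1	H2-T3|TLA
MH1-T9	alpha	1	H2-T9
MH1-T10	alpha	1	H2-T10
MH1-T11	alpha	1	H2-T11
MH1-T15	alpha	1	H2-T15
MH1-T18	alpha	1	H2-T18
MH1-T22	alpha	1	H2-T22
MH1-T23	alpha	1	H2-T23|QA-1
MH2-AA	alpha	2	H2-AA|H2-IAA
MH2-AB1	beta	2	H2-AB1|H2-AB|H2-IAB
MH2-EA	alpha	2	H2-EA|H2-IEA
MH2-EB1	beta	2	H2-EB1|H2-EB|H2-IEB
MH2-EB2	beta	2	H2-EB2
MH2-DMA	alpha	2	H2-DMA|H2-MA
MH2-DMB1	beta	2	H2-DMB1|H2-MB1
MH2-DMB2	beta	2	H2-DMB2|H2-MB2
MH2-OA	alpha	2	H2-OA
MH2-OB	beta	2	H2-OB
B2M	beta	1	BETA-2-MICROGLOBULIN|B2-MICROGLOBULIN
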