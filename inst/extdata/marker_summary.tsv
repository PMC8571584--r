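marker	class	N	L	S	h_or_a	hd	pi
cox1	mitochondrial	225	577	18	12	0.843	0.01301
cytb	mitochondrial	230	877	50	48	0.951	0.01394
CR	mitochondrial	181	307	80	98	0.993	0.07497
tpm	nuclear	184	427	2	3	NA	0.00011
irf2	nuclear	182	542	6	6	NA	0.00048
csde	nuclear	223	542	15	13	NA	0.0006
pax	nuclear	255	515	9	10	NA	0.00159
rag1	nuclear	162	1323	29	65	NA	0.00337
bfib	nuclear	92	1067	50	53	NA	0.0083
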