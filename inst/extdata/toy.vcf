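##fileformat=VCFv4.2
##source=glacomp-toy
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##contig=<ID=Chr01>
##contig=<ID=Chr02>
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	WA_001	WA_002	LR_001	LR_002	RC_001	RC_002
Chr01	1001	.	A	G	.	PASS	.	GT	0/0	0/0	1/1	1/1	1/1	1/1
Chr01	1501	.	C	T	.	PASS	.	GT	0/0	0/0	1/1	1/1	1/1	1/1
Chr01	250001	.	G	A	.	PASS	.	GT	0/0	1/1	0/0	1/1	0/0	1/1
Chr01	250501	.	T	C	.	PASS	.	GT	0/0	1/1	0/0	0/1	0/0	1/1
Chr02	2001	.	A	C	.	PASS	.	GT	0/0	0/0	0/0	1/1	1/1	./.
Chr02	2501	.	C	G	.	PASS	.	GT	1/1	0/0	1/1	0/0	0/0	0/0
Chr02	400001	.	G	T	.	PASS	.	GT	0/0	0/0	0/0	0/0	1/1	1/1
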