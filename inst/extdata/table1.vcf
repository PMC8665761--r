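##fileformat=VCFv4.2
##contig=<ID=example,length=18>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s1	s2	s3	s4	s5
example	1	a	T	TAA	.	PASS	.	GT	0	0	1	1	0
example	4	b	TGG	AAAAAA	.	PASS	.	GT	1	1	0	0	1
example	5	c	G	CC	.	PASS	.	GT	0	0	1	1	0
example	12	d	AGTTA	T	.	PASS	.	GT	0	0	0	1	1
example	16	e	AC	T,A	.	PASS	.	GT	0	1	2	0	0
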