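##fileformat=VCFv4.2
##contig=<ID=5,length=181538259>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	sampleA	sampleB
5	373100	rs001	A	G	.	PASS	.	GT	0/1	1/1
5	373500	rs002	C	T	.	PASS	.	GT	0/0	0/1
5	374200	rs003	G	A	.	PASS	.	GT	1/1	0/0
5	375000	rs004	T	C,G	.	PASS	.	GT	1/2	0/1
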