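##fileformat=VCFv4.2
##contig=<ID=chr1,length=100000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	p1a	p1b	p2a	p2b	p3a	p3b	p4a	p4b
chr1	101	.	A	G	.	PASS	.	GT	0|0	0|0	1|1	1|1	1|1	1|1	0|0	0|0
chr1	205	.	C	T	.	PASS	.	GT	1|1	1|1	0|0	0|0	1|1	1|1	0|0	0|0
chr1	310	.	G	A	.	PASS	.	GT	0|0	0|0	0|1	1|1	0|1	1|0	0|0	0|0
chr1	488	.	T	C	.	PASS	.	GT	0|0	0|0	1|1	1|1	1|1	1|1	0|1	0|0
chr1	602	.	A	C,G	.	PASS	.	GT	0|0	0|0	1|1	1|1	2|2	2|2	0|0	0|0
chr1	777	.	G	T	.	PASS	.	GT	0|0	0|0	0|0	0|0	0|0	0|0	0|0	0|0
chr1	915	.	A	AT	.	PASS	.	GT	0|0	0|0	1|1	1|1	1|1	1|1	0|0	0|0
chr1	1040	.	C	G	.	PASS	.	GT	./.	./.	1|1	1|1	1|1	1|1	0|0	0|0
chr1	1337	.	T	A	.	PASS	.	GT	0|0	0|1	1|1	1|0	1|1	1|1	0|0	0|1
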