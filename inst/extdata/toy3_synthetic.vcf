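##fileformat=VCFv4.2
##source=hand-written synthetic toy (3 haploid samples, 5 variant records)
##contig=<ID=synth_Y,length=2000>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	m1	m2	m3
synth_Y	101	.	A	T	.	PASS	.	GT	0	1	1
synth_Y	440	.	C	G	.	PASS	.	GT	1	0	0
synth_Y	441	.	G	A,C	.	PASS	.	GT	1	0	2
synth_Y	902	.	T	C	.	PASS	.	GT	0	0	1
synth_Y	1500	.	A	G	.	PASS	.	GT	1	1	1
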