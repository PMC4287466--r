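##fileformat=VCFv4.2
##source=synthetic toy fixture (two haploid parent strains)
##INFO=<ID=MAT,Number=0,Type=Flag,Description="Mating-type locus">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	strainA	strainB
chr1	1200	.	A	T	.	PASS	.	GT	0	1
chr1	3400	.	C	G	.	PASS	.	GT	1	0
chr1	5000	.	G	A,T	.	PASS	.	GT	1	2
chr2	700	.	T	C	.	PASS	.	GT	0	.
chr2	2100	.	G	C	.	PASS	.	GT	1	0
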