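##fileformat=VCFv4.2
##source=hand-built QC fixture: one SNP violates each rule, two pass
##INFO=<ID=FRAG,Number=1,Type=String,Description="Fragment id">
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	s01	s02	s03	s04	s05	s06	s07	s08	s09	s10	s11	s12	s13	s14	s15	s16	s17	s18	s19	s20
frag01	5	frag01_05	A	G	.	PASS	FRAG=frag01	GT	1/1	1/1	1/1	1/1	0/1	0/1	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
frag01	9	frag01_09	C	T	.	PASS	FRAG=frag01	GT	0/1	0/1	0/1	0/1	0/1	1/1	1/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
frag02	3	frag02_03	G	A,T	.	PASS	FRAG=frag02	GT	0/2	1/2	0/1	0/1	0/1	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
frag03	7	frag03_07	A	C	.	PASS	FRAG=frag03	GT	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1	0/1
frag04	2	frag04_02	T	A	.	PASS	FRAG=frag04	GT	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	./.	0/1	0/1	0/1	0/0	0/0	0/0	1/1	1/1	1/1
frag05	4	frag05_04	C	G	.	PASS	FRAG=frag05	GT	0/1	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0	0/0
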