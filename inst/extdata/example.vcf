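##fileformat=VCFv4.2
##contig=<ID=chr1>
##contig=<ID=chr2>
##contig=<ID=chr3>
##contig=<ID=chr7>
##contig=<ID=chr12>
##contig=<ID=chrX>
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	IS01	IS01_fa	IS01_mo	IS02	IS02_fa	IS02_mo	IS03	IS03_fa	IS03_mo	IS04	IS04_fa	IS04_mo	IS05	IS05_fa	IS05_mo	IS06	IS06_fa	IS06_mo	IS07	IS08	IS09	IS10	IS11	IS12	IS13	IS14	IS15	IS16
chr1	181000000	.	A	C	100	PASS	.	GT:AD	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/1:38,34	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0
chr2	240000000	.	A	T	100	PASS	.	GT:AD	0/1:28,32	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0
chr3	7000000	.	C	T	100	PASS	.	GT:AD	0/0:30,0	0/0:30,0	0/0:30,0	0/1:36,33	0/1:25,25	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0
chr3	7050000	.	C	T	100	PASS	.	GT:AD	0/0:30,0	0/0:30,0	0/0:30,0	0/1:32,31	0/0:30,0	0/1:27,26	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0
chr7	105000000	.	C	T	100	PASS	.	GT:AD	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/1:36,35	0/0:30,0
chr12	24000000	.	C	T	100	PASS	.	GT:AD	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/1:29,28	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0	0/0:30,0
chrX	50000000	.	A	G	100	PASS	.	GT:AD	0:31,0	0:31,0	0/0:30,0	0/0:30,0	0:31,0	0/0:30,0	0:31,0	0:31,0	0/0:30,0	0/0:30,0	0:31,0	0/0:30,0	0/0:30,0	0:31,0	0/0:30,0	1:0,38	0:31,0	0/1:30,28	0/0:30,0	0:31,0	0/0:30,0	0:31,0	0/0:30,0	0:31,0	0/0:30,0	0:31,0	0/0:30,0	0:31,0
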