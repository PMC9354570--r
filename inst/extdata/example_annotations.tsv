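chrom	pos	ref	alt	gene	consequence	af_gnomad_v2	af_gnomad_v3	af_kaviar	af_krgdb	af_togovar	af_inhouse	cadd	rf_score	ada_score	cadd_splice_flag	acmg_class	clinvar_reported	in_repeat_or_segdup
chr2	240000000	A	T	HDAC4	stopgain	.	.	.	.	.	.	42.0	.	.	FALSE	P	FALSE	FALSE
chr3	7000000	C	T	GRM7	nonsynonymous_snv	.	.	.	.	.	.	26.7	.	.	FALSE	LP	FALSE	FALSE
chr3	7050000	C	T	GRM7	nonsynonymous_snv	.	.	.	.	.	.	25.8	.	.	FALSE	LP	TRUE	FALSE
chr12	24000000	C	T	SOX5	intronic	.	.	.	.	.	.	17.9	.	.	FALSE	VUS	FALSE	FALSE
chrX	50000000	A	G	SHROOM4	intronic	.	.	.	.	.	.	21.2	0.68	0.72	TRUE	VUS	FALSE	FALSE
chr1	181000000	A	C	CACNA1E	nonsynonymous_snv	.	.	.	.	.	.	24.1	.	.	FALSE	LP	TRUE	FALSE
chr7	105000000	C	T	KMT2E	stopgain	.	.	.	.	.	.	39.0	.	.	FALSE	P	FALSE	FALSE
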