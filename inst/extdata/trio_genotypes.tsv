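# Trio genotype configurations of the 29 diagnosed cases (one row per variant;
# compound-heterozygous cases and the two-gene double-heterozygous case 32 carry two rows).
# ref/alt for indels and the 1p36.33 duplication are N-anchored placeholders: the source
# listing prints genomic start positions and cDNA notation, not VCF alleles. Genotypes,
# genes, positions and inheritance labels are as listed.
# af_pop is 0 for all rows (variants are absent from population databases / ultra-rare;
# per-variant frequencies are not published).
case_id	gene	chrom	pos	ref	alt	consequence	clinical_class	af_pop	gt_proband	gt_mother	gt_father
2	ACTC1	chr15	35085595	T	C	missense	likely_pathogenic	0	het	hom_ref	het
3	TNNT2	chr1	201331116	C	T	missense	pathogenic	0	het	hom_ref	hom_ref
5	PTPN11	chr12	112888202	C	T	missense	pathogenic	0	het	hom_ref	hom_ref
6	RAF1	chr3	12645682	NNNN	N	inframe	pathogenic	0	het	hom_ref	hom_ref
7	PRKAG2	chr7	151257696	C	T	missense	pathogenic	0	het	hom_ref	hom_ref
8	TNNI3	chr19	55668662	A	T	splice	likely_pathogenic	0	hom_alt	het	het
12	HADHB	chr2	26502860	A	G	splice	likely_pathogenic	0	hom_alt	het	het
13	GAA	chr17	78078910	NN	N	lof	pathogenic	0	het	hom_ref	het
13	GAA	chr17	78090909	G	A	splice	pathogenic	0	het	het	hom_ref
14	HCCS	chrX	11139015	G	A	splice	likely_pathogenic	0	het	hom_ref	hom_ref
17	PTPN11	chr12	112926270	C	T	missense	pathogenic	0	het	hom_ref	hom_ref
18	RAF1	chr3	12645699	G	A	missense	pathogenic	0	het	hom_ref	hom_ref
19	FAH	chr15	80450512	G	T	missense	pathogenic	0	hom_alt	het	het
20	GAA	chr17	78078910	NN	N	lof	pathogenic	0	het	hom_ref	het
20	GAA	chr17	78079671	C	T	missense	pathogenic	0	het	het	hom_ref
21	HADHB	chr2	26505741	NN	N	lof	likely_pathogenic	0	het	het	hom_ref
21	HADHB	chr2	26502860	A	G	splice	likely_pathogenic	0	het	hom_ref	het
22	TAZ	chrX	153640263	NNNNN	N	lof	likely_pathogenic	0	hemi	het	hom_ref
24	VPS33A	chr12	122717464	G	A	missense	pathogenic	0	hom_alt	het	het
26	POU1F1	chr3	87310439	G	A	lof	likely_pathogenic	0	hom_alt	het	het
27	PTPN11	chr12	112926908	C	G	missense	pathogenic	0	het	hom_ref	hom_ref
28	HRAS	chr11	534288	C	T	missense	pathogenic	0	het	hom_ref	hom_ref
30	ATAD3A	chr1	1392270	N	<DUP>	other	pathogenic	0	het	hom_ref	hom_ref
32	MYL2	chr12	111356937	C	T	missense	pathogenic	0	het	het	hom_ref
32	MYH7	chr14	23887522	C	T	missense	pathogenic	0	het	hom_ref	het
33	PTPN11	chr12	112910827	A	G	missense	pathogenic	0	het	hom_ref	hom_ref
35	MYH7	chr14	23886789	C	T	missense	likely_pathogenic	0	het	het	hom_ref
36	MYH7	chr14	23886717	C	T	missense	likely_pathogenic	0	het	hom_ref	hom_ref
37	MYH7	chr14	23887513	G	A	missense	likely_pathogenic	0	het	hom_ref	het
38	PTPN11	chr12	112910827	A	G	missense	pathogenic	0	het	hom_ref	hom_ref
40	NONO	chrX	70514185	C	T	lof	pathogenic	0	hemi	het	hom_ref
41	TNNI3	chr19	55667648	NN	N	lof	likely_pathogenic	0	hom_alt	het	het
42	TNNI3	chr19	55667648	NN	N	lof	likely_pathogenic	0	hom_alt	het	het
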