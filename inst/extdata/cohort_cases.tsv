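# Infantile cardiomyopathy trio-WES cohort, 42 consecutive probands (<= 12 months).
# record_source = case_report: per-case diagnostic record transcribed from the study's
#   case listing (case_id is the listed patient ID).
# record_source = margin_synthetic: undiagnosed case reconstructed by the package so that
#   every published aggregate margin (per-setting sex, CM type, CM class, age mean/median,
#   family history and prenatal-detection totals) is satisfied; individual field values of
#   these rows are synthetic.
# cm_class: isolated | syndromic | metabolic (syndromic + metabolic = "complex").
# zygosity: hetero | homo | hemi | compound_het; parental_origin: de_novo | mother | father | both.
# t1_days/t2_days: per-case turnaround is not published; stored as NA by design.
case_id	urgent	age_months	sex	cm_type	cm_class	diagnosed	gene	zygosity	parental_origin	family_history	prenatal_detection	t1_days	t2_days	record_source
2	FALSE	7	M	DCM	isolated	TRUE	ACTC1	hetero	father	FALSE	FALSE	NA	NA	case_report
3	FALSE	3	F	DCM	isolated	TRUE	TNNT2	hetero	de_novo	FALSE	TRUE	NA	NA	case_report
5	TRUE	1	M	HCM	isolated	TRUE	PTPN11	hetero	de_novo	FALSE	FALSE	NA	NA	case_report
6	FALSE	1	M	HCM	syndromic	TRUE	RAF1	hetero	de_novo	FALSE	FALSE	NA	NA	case_report
7	TRUE	1	M	HCM	syndromic	TRUE	PRKAG2	hetero	de_novo	FALSE	FALSE	NA	NA	case_report
8	TRUE	12	F	DCM	isolated	TRUE	TNNI3	homo	both	FALSE	TRUE	NA	NA	case_report
12	TRUE	4	F	HCM	metabolic	TRUE	HADHB	homo	both	TRUE	FALSE	NA	NA	case_report
13	TRUE	6	F	HCM	isolated	TRUE	GAA	compound_het	both	FALSE	FALSE	NA	NA	case_report
14	TRUE	3	F	HCM	syndromic	TRUE	HCCS	hetero	de_novo	FALSE	FALSE	NA	NA	case_report
17	FALSE	1	F	HCM	syndromic	TRUE	PTPN11	hetero	de_novo	TRUE	FALSE	NA	NA	case_report
18	FALSE	0	M	HCM	syndromic	TRUE	RAF1	hetero	de_novo	FALSE	FALSE	NA	NA	case_report
19	TRUE	3	M	HCM	metabolic	TRUE	FAH	homo	both	FALSE	TRUE	NA	NA	case_report
20	TRUE	10	F	HCM	metabolic	TRUE	GAA	compound_het	both	FALSE	FALSE	NA	NA	case_report
21	TRUE	1	F	HCM	metabolic	TRUE	HADHB	compound_het	both	FALSE	FALSE	NA	NA	case_report
22	TRUE	9	M	DCM	metabolic	TRUE	TAZ	hemi	mother	FALSE	FALSE	NA	NA	case_report
24	TRUE	11	M	HCM	metabolic	TRUE	VPS33A	homo	both	FALSE	FALSE	NA	NA	case_report
26	TRUE	3	M	HCM	metabolic	TRUE	POU1F1	homo	both	FALSE	FALSE	NA	NA	case_report
27	TRUE	0	M	HCM	syndromic	TRUE	PTPN11	hetero	de_novo	FALSE	FALSE	NA	NA	case_report
28	TRUE	0	M	HCM	syndromic	TRUE	HRAS	hetero	de_novo	FALSE	FALSE	NA	NA	case_report
30	TRUE	1	F	HCM	metabolic	TRUE	ATAD3A	hetero	de_novo	FALSE	TRUE	NA	NA	case_report
32	FALSE	0	M	HCM	isolated	TRUE	MYL2;MYH7	hetero	both	FALSE	FALSE	NA	NA	case_report
33	FALSE	5	M	HCM	syndromic	TRUE	PTPN11	hetero	de_novo	FALSE	FALSE	NA	NA	case_report
35	FALSE	2	M	DCM	isolated	TRUE	MYH7	hetero	mother	FALSE	FALSE	NA	NA	case_report
36	FALSE	12	M	HCM	isolated	TRUE	MYH7	hetero	de_novo	FALSE	FALSE	NA	NA	case_report
37	FALSE	7	M	DCM	isolated	TRUE	MYH7	hetero	father	FALSE	FALSE	NA	NA	case_report
38	FALSE	8	F	HCM	syndromic	TRUE	PTPN11	hetero	de_novo	FALSE	FALSE	NA	NA	case_report
40	FALSE	3	M	DCM	syndromic	TRUE	NONO	hemi	mother	FALSE	TRUE	NA	NA	case_report
41	TRUE	9	F	DCM	isolated	TRUE	TNNI3	homo	both	TRUE	FALSE	NA	NA	case_report
42	TRUE	10	F	DCM	isolated	TRUE	TNNI3	homo	both	TRUE	FALSE	NA	NA	case_report
U1	TRUE	0	M	HCM	syndromic	FALSE	NA	NA	NA	FALSE	FALSE	NA	NA	margin_synthetic
U2	TRUE	1	M	HCM	syndromic	FALSE	NA	NA	NA	FALSE	FALSE	NA	NA	margin_synthetic
U3	TRUE	2	M	HCM	syndromic	FALSE	NA	NA	NA	FALSE	FALSE	NA	NA	margin_synthetic
U4	TRUE	2	F	DCM	syndromic	FALSE	NA	NA	NA	FALSE	TRUE	NA	NA	margin_synthetic
U5	TRUE	3	F	HCM	syndromic	FALSE	NA	NA	NA	FALSE	FALSE	NA	NA	margin_synthetic
U6	TRUE	5	M	HCM	metabolic	FALSE	NA	NA	NA	FALSE	TRUE	NA	NA	margin_synthetic
U7	TRUE	6	F	HCM	metabolic	FALSE	NA	NA	NA	FALSE	FALSE	NA	NA	margin_synthetic
N1	FALSE	0	M	DCM	isolated	FALSE	NA	NA	NA	FALSE	TRUE	NA	NA	margin_synthetic
N2	FALSE	2	M	HCM	syndromic	FALSE	NA	NA	NA	FALSE	FALSE	NA	NA	margin_synthetic
N3	FALSE	3	M	HCM	syndromic	FALSE	NA	NA	NA	FALSE	FALSE	NA	NA	margin_synthetic
N4	FALSE	4	M	HCM	syndromic	FALSE	NA	NA	NA	FALSE	FALSE	NA	NA	margin_synthetic
N5	FALSE	4	F	DCM	syndromic	FALSE	NA	NA	NA	TRUE	TRUE	NA	NA	margin_synthetic
N6	FALSE	4	M	HCM	metabolic	FALSE	NA	NA	NA	FALSE	FALSE	NA	NA	margin_synthetic
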