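# Cardiomyopathy gene panel (green-list style): symbol, inheritance modes,
# expected pathogenic mechanism, phenotype tags.
# mechanism: lof = loss of function expected; non_lof = gain-of-function/dominant-negative
# (truncating alleles are not the disease mechanism); either = both reported.
symbol	inheritance_modes	mechanism	phenotype_tags
ACTC1	AD	either	HCM,DCM
TNNT2	AD	either	HCM,DCM
TNNI3	AD,AR	either	HCM,DCM
MYH7	AD	either	HCM,DCM
MYL2	AD	either	HCM
MYBPC3	AD	either	HCM
TPM1	AD	either	HCM,DCM
PTPN11	AD	non_lof	HCM
RAF1	AD	non_lof	HCM
HRAS	AD	non_lof	HCM
PRKAG2	AD	either	HCM
GAA	AR	either	HCM
HADHB	AR	lof	HCM
FAH	AR	either	HCM
ACADVL	AR	lof	HCM,DCM
VPS33A	AR	either	HCM
POU1F1	AR	lof	HCM
TAZ	XL	lof	DCM
LAMP2	XL	lof	HCM
NONO	XL	lof	DCM
HCCS	AD,XL	lof	HCM
ATAD3A	AD	either	HCM
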