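# 12-SNP BMI risk-variant panel (candidate loci established 2007-2009 GWAS waves).
# Columns rsid/chromosome/position/locus_name/risk_allele/overall_risk_freq follow the
# study's association table; risk_freq_uk / risk_freq_nl are the per-cohort
# risk-allele frequencies and overall_risk_freq their mean.
# other_allele is NOT printed in the source table: values below are the SNPs'
# standard biallelic partners (dbSNP convention). rs9939609 is an A/T SNP and
# therefore strand-ambiguous.
# info_quality: imputation info for SNPs derived from the imputed control array
# (NA = directly genotyped by TaqMan assay in both cohorts). The source text maps
# rs10838738 to MTCH2 in its table but calls it MC4R in the genotyping methods;
# this fixture follows the table.
rsid	chromosome	position	locus_name	risk_allele	other_allele	risk_freq_uk	risk_freq_nl	overall_risk_freq	info_quality
rs4074134	11	27603861	BDNF	G	A	0.79	0.79	0.79	0.99
rs7138803	12	48533735	FAIM2	A	G	0.38	0.37	0.375	0.99
rs7647305	3	187316984	ETV5	C	T	0.78	0.80	0.79	0.99
rs9939609	16	52378028	FTO	A	T	0.42	0.36	0.39	NA
rs10938397	4	44877284	GNPDA2	G	A	0.45	0.42	0.435	NA
rs11084753	19	39013977	KCTD15	G	A	0.68	0.66	0.67	0.94
rs17782313	18	56002077	MC4R	C	T	0.24	0.25	0.245	NA
rs10838738	11	47619625	MTCH2	G	A	0.36	0.33	0.345	0.99
rs2815752	1	72585028	NEGR1	A	G	0.60	0.61	0.605	NA
rs10913469	1	176180142	SEC16B	C	T	0.21	0.20	0.205	0.99
rs7498665	16	28790742	SH2B1	G	A	0.39	0.40	0.395	0.99
rs6548238	2	624905	TMEM18	C	T	0.84	0.83	0.835	0.95
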