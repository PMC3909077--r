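# Published per-cohort association results for rs7498665 (SH2B1 locus):
# odds ratio per risk allele with 95% CI, one row per case-control set.
# Transcribed input for the meta-analysis-from-published-tables pathway.
cohort	rsid	or	ci_low	ci_high
UK	rs7498665	1.04	0.88	1.22
NL	rs7498665	0.79	0.69	0.90
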