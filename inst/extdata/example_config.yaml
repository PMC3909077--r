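# End-to-end example run: two synthetic BMI-matched case-control sets shaped
# like the UK (563/791) and Dutch (510/2720) study samples, genotyped on the
# packaged 12-SNP BMI panel with ~5% missingness, analysed under the null
# (per-allele OR 1 for every SNP).
seed: 20140131
output_dir: results/pipeline
panel: default
cohorts:
  UK:
    n_cases: 563
    n_controls: 791
    missing_rate: 0.05
  NL:
    n_cases: 510
    n_controls: 2720
    missing_rate: 0.05
meta:
  i2_threshold: 0.25
grs:
  min_completeness: 0.9
bmi_threshold: 30
power:
  - {freq: 0.2, or: 1.3, alpha: 0.05, n_cases: 1073, n_controls: 3511}
figure: true
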