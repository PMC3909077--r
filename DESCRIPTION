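Package: pcosgrs
Title: Candidate-SNP Association, Meta-Analysis and Counted Genetic Risk
    Scores for BMI-Matched PCOS Case-Control Studies
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for a candidate-gene case-control analysis of
    BMI-associated variants in polycystic ovary syndrome (PCOS):
    Rotterdam 2003 phenotype classification (free androgen index,
    hirsutism, polycystic ovarian morphology), PLINK text and dosage
    genotype input with Hardy-Weinberg and call-rate quality control,
    per-SNP additive-model logistic association, inverse-variance
    fixed-effect and DerSimonian-Laird random-effects meta-analysis with
    an I-squared model-switching rule, an unweighted counted genetic risk
    score with binned odds ratios and a rank-based trend test, analytic
    case-control power for the allelic test, and a synthetic-cohort
    generator (Hardy-Weinberg genotypes, logistic-additive disease model,
    Rotterdam-style phenotypes) so the whole chain is testable without
    subject-level study data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    metafor,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
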