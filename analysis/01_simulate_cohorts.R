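#!/usr/bin/env Rscript
# Stage 1: build the two synthetic BMI-matched case-control sets the rest of
# the analysis runs on — UK-shaped (563 cases / 791 controls) and Dutch-shaped
# (510 / 2720) — on the packaged 12-SNP BMI panel, with ~5% genotype
# missingness and null per-allele effects. Writes dosage + phenotype TSVs and
# a PLINK text copy of the UK set under results/analysis/.

library(pcosgrs)

out <- "results/analysis"
dir.create(out, recursive = TRUE, showWarnings = FALSE)
panel <- bmi_panel()
seed <- 20140131

sets <- list(UK = c(cases = 563, controls = 791),
             NL = c(cases = 510, controls = 2720))
for (lab in names(sets)) {
  spec <- sim_spec(sets[[lab]]["cases"], sets[[lab]]["controls"], panel,
                   per_allele_or = 1, missing_rate = 0.05,
                   seed = seed + match(lab, names(sets)))
  coh <- simulate_cohort(spec, label = lab)
  write_dosage_tsv(coh, file.path(out, sprintf("dosage_%s.tsv", lab)))
  ph <- cbind(data.frame(id = coh$ids, status = coh$status, bmi = coh$bmi),
              simulate_phenotypes(coh$status, derive_seed(spec$seed, "phenotypes")))
  write_phenotype_tsv(ph, file.path(out, sprintf("phenotype_%s.tsv", lab)))
  cat(sprintf("%s: %d cases / %d controls, %.1f%% missing genotypes\n",
              lab, sum(coh$status == 1), sum(coh$status == 0),
              100 * mean(is.na(coh$dosages))))
}

# PLINK text copy of the UK set (hard calls), for the .ped/.map pathway
uk <- read_dosage_tsv(file.path(out, "dosage_UK.tsv"), panel,
                      file.path(out, "phenotype_UK.tsv"), label = "UK")
write_ped_map(uk, panel, file.path(out, "uk"))
cat("wrote", file.path(out, "uk.ped"), "/ .map\n")

# sanity: the simulated phenotype measures reproduce case status through the
# Rotterdam 2-of-3 classifier
ph <- read_phenotype_tsv(file.path(out, "phenotype_UK.tsv"))
cls <- classify_rotterdam(ph)
cat(sprintf("Rotterdam classifier agreement with simulated status: %.1f%%\n",
            100 * mean(cls$pcos == (ph$status == 1))))
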