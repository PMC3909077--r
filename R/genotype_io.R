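#' Genotype input/output and quality control
#'
#' Readers and writers for PLINK text pedigree files and plain dosage
#' matrices, plus the two QC gates applied to candidate-SNP data: per-SNP /
#' per-individual call rate and the Hardy-Weinberg exact test. Dosages are
#' always the count of the panel's risk allele, regardless of which allele a
#' file lists first.
#'
#' @name genotype_io
NULL

# ---- PLINK text .ped / .map ------------------------------------------------

#' Read a PLINK text .ped/.map pair into a cohort
#'
#' Whitespace-delimited PLINK text format: the .map file has columns
#' chromosome, rsid, genetic distance, position; the .ped file has the six
#' leading columns (FID, IID, PAT, MAT, SEX, PHENO with 1 = control,
#' 2 = case) followed by two allele columns per SNP, `0` marking a missing
#' allele. Genotypes are converted to risk-allele dosages using the panel's
#' risk/other alleles; any allele not matching the panel raises an error
#' naming the SNP. Strand-ambiguous panel SNPs (A/T, C/G) trigger a warning.
#'
#' @param ped,map paths to the .ped and .map files.
#' @param panel a [variant_panel].
#' @param label cohort label.
#' @return a [new_cohort()] object (no BMI; join a phenotype table for that).
#' @export
read_ped_map <- function(ped, map, panel, label = "cohort") {
  panel <- validate_panel(panel)
  if (!file.exists(ped)) .stopf(".ped file not found: %s", ped)
  if (!file.exists(map)) .stopf(".map file not found: %s", map)
  mp <- utils::read.table(map, stringsAsFactors = FALSE,
                          col.names = c("chromosome", "rsid", "cm", "position"))
  snps <- intersect(panel$rsid, mp$rsid)
  if (!length(snps)) .stopf("no panel SNPs found in %s", map)
  dropped <- setdiff(panel$rsid, mp$rsid)
  if (length(dropped))
    warning(sprintf("panel SNPs absent from map: %s", paste(dropped, collapse = ", ")))
  amb <- strand_ambiguous(panel)[panel$rsid %in% snps]
  if (any(amb))
    warning(sprintf("strand-ambiguous (A/T or C/G) panel SNPs read as-is: %s",
                    paste(snps[amb], collapse = ", ")))

  pd <- utils::read.table(ped, stringsAsFactors = FALSE, colClasses = "character")
  if (ncol(pd) != 6 + 2 * nrow(mp))
    .stopf(".ped has %d columns, expected %d for %d map SNPs",
           ncol(pd), 6 + 2 * nrow(mp), nrow(mp))
  pheno <- as.integer(pd[[6]])
  if (!all(pheno %in% c(1L, 2L)))
    .stopf(".ped phenotype must be 1 (control) or 2 (case)")

  dos <- matrix(NA_real_, nrow(pd), length(snps), dimnames = list(NULL, snps))
  for (j in seq_along(snps)) {
    k <- match(snps[j], mp$rsid)
    a1 <- pd[[6 + 2 * k - 1]]
    a2 <- pd[[6 + 2 * k]]
    risk  <- panel$risk_allele[match(snps[j], panel$rsid)]
    other <- panel$other_allele[match(snps[j], panel$rsid)]
    miss <- a1 == "0" | a2 == "0"
    bad <- !miss & (!(a1 %in% c(risk, other)) | !(a2 %in% c(risk, other)))
    if (any(bad))
      .stopf("unknown allele(s) '%s' at %s (panel alleles %s/%s)",
             paste(unique(c(a1[bad], a2[bad])), collapse = ","),
             snps[j], risk, other)
    dos[, j] <- ifelse(miss, NA_real_, (a1 == risk) + (a2 == risk))
  }
  new_cohort(pd[[2]], dos, pheno - 1L, bmi = NULL, label = label)
}

#' Write a cohort as PLINK text .ped/.map
#'
#' Hard-call genotypes only: fractional (imputed) dosages cannot be expressed
#' as two alleles and raise an error — write those with
#' [write_dosage_tsv()]. Missing genotypes are written as `0 0`.
#'
#' @param cohort a cohort.
#' @param panel the panel the dosages were coded against.
#' @param prefix output path prefix; writes `<prefix>.ped` and `<prefix>.map`.
#' @return the two paths, invisibly.
#' @export
write_ped_map <- function(cohort, panel, prefix) {
  panel <- validate_panel(panel)
  snps <- colnames(cohort$dosages)
  pi <- match(snps, panel$rsid)
  if (anyNA(pi)) .stopf("cohort SNPs missing from panel: %s",
                        paste(snps[is.na(pi)], collapse = ", "))
  d <- cohort$dosages
  if (any(!is.na(d) & d != round(d)))
    .stopf("fractional dosages cannot be written as .ped hard calls; use write_dosage_tsv()")
  map <- data.frame(chromosome = panel$chromosome[pi], rsid = snps,
                    cm = 0L, position = panel$position[pi])
  utils::write.table(map, paste0(prefix, ".map"), sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  allele_cols <- vector("list", length(snps))
  for (j in seq_along(snps)) {
    risk <- panel$risk_allele[pi[j]]; other <- panel$other_allele[pi[j]]
    g <- d[, j]
    a1 <- ifelse(is.na(g), "0", ifelse(g >= 1, risk, other))
    a2 <- ifelse(is.na(g), "0", ifelse(g == 2, risk, other))
    allele_cols[[j]] <- cbind(a1, a2)
  }
  ped <- cbind(cohort$ids, cohort$ids, "0", "0", "0",
               as.character(cohort$status + 1L), do.call(cbind, allele_cols))
  utils::write.table(ped, paste0(prefix, ".ped"), sep = " ", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(c(ped = paste0(prefix, ".ped"), map = paste0(prefix, ".map")))
}

# ---- dosage TSV ------------------------------------------------------------

#' Read a dosage TSV (plus phenotype table) into a cohort
#'
#' The dosage TSV has an `id` column followed by one column per rsID holding
#' risk-allele dosages in `[0, 2]`; fractional values (imputed expected
#' dosages) pass through unchanged, `NA` marks missing. Case status and BMI
#' come from a phenotype TSV (see [read_phenotype_tsv()]) joined on `id`.
#'
#' @param path dosage TSV path.
#' @param panel a [variant_panel]; only panel SNPs are kept.
#' @param phenotype_path phenotype TSV path with at least `id` and `status`.
#' @param label cohort label.
#' @return a cohort.
#' @export
read_dosage_tsv <- function(path, panel, phenotype_path, label = "cohort") {
  panel <- validate_panel(panel)
  d <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE,
                         check.names = FALSE)
  if (!"id" %in% names(d)) .stopf("dosage TSV needs an 'id' column")
  snps <- intersect(panel$rsid, names(d))
  if (!length(snps)) .stopf("no panel SNPs among dosage TSV columns")
  m <- as.matrix(d[, snps, drop = FALSE])
  storage.mode(m) <- "double"
  ph <- read_phenotype_tsv(phenotype_path)
  k <- match(d$id, ph$id)
  if (anyNA(k)) .stopf("ids absent from phenotype table: %s",
                       paste(utils::head(d$id[is.na(k)]), collapse = ", "))
  new_cohort(d$id, m, ph$status[k],
             bmi = if ("bmi" %in% names(ph)) ph$bmi[k], label = label)
}

#' Write a cohort's dosage matrix as TSV
#'
#' @param cohort a cohort.
#' @param path output path.
#' @export
write_dosage_tsv <- function(cohort, path) {
  out <- data.frame(id = cohort$ids, cohort$dosages, check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     na = "NA")
  invisible(path)
}

# ---- QC --------------------------------------------------------------------

#' Hardy-Weinberg exact test
#'
#' Exact conditional (Levene-Haldane) test: given the observed allele counts,
#' the p-value is the total probability of all heterozygote counts whose
#' conditional probability does not exceed that of the observed count.
#' Applied to hard-call genotype counts; fractional dosages should be rounded
#' first (the QC report does this with a warning).
#'
#' @param n_hom_risk,n_het,n_hom_other genotype counts (risk-allele
#'   homozygote, heterozygote, other homozygote).
#' @return the exact p-value.
#' @export
hwe_exact_test <- function(n_hom_risk, n_het, n_hom_other) {
  cnt <- c(n_hom_risk, n_het, n_hom_other)
  if (any(cnt < 0) || any(cnt != round(cnt))) .stopf("genotype counts must be non-negative integers")
  n <- sum(cnt)
  if (n == 0) .stopf("all genotype counts are zero")
  n_rare <- min(2 * n_hom_risk + n_het, 2 * n_hom_other + n_het)
  if (n_rare == 0) return(1.0)  # monomorphic: single attainable configuration
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  # log P(h heterozygotes | allele counts), Levene-Haldane
  logp <- function(h) {
    hom_r <- (n_rare - h) / 2
    hom_c <- n - h - hom_r
    h * log(2) + lfactorial(n) - lfactorial(h) - lfactorial(hom_r) -
      lfactorial(hom_c) + lfactorial(n_rare) + lfactorial(2 * n - n_rare) -
      lfactorial(2 * n)
  }
  lp <- vapply(hets, logp, 0)
  p_obs <- lp[match(n_het, hets)]
  sum(exp(lp[lp <= p_obs + 1e-10]))
}

#' Call rates and QC flags for a cohort
#'
#' Non-missing proportions per SNP and per individual; SNPs below the
#' call-rate threshold are flagged, and each SNP gets a Hardy-Weinberg exact
#' p-value computed from (rounded) hard calls.
#'
#' @param cohort a cohort.
#' @param threshold per-SNP call-rate flag threshold (default 0.95, the
#'   study's genotyping success floor).
#' @return list with `per_snp`, `per_individual`, `flagged_snps` and `hwe`
#'   (data frame of genotype counts and p-values).
#' @export
call_rate <- function(cohort, threshold = 0.95) {
  d <- cohort$dosages
  if (!length(d)) .stopf("empty dosage matrix")
  per_snp <- colMeans(!is.na(d))
  per_ind <- rowMeans(!is.na(d))
  names(per_ind) <- cohort$ids
  if (any(!is.na(d) & d != round(d)))
    warning("fractional dosages rounded to hard calls for HWE testing")
  hwe <- do.call(rbind, lapply(colnames(d), function(s) {
    g <- round(d[, s]); g <- g[!is.na(g)]
    cnt <- c(sum(g == 2), sum(g == 1), sum(g == 0))
    data.frame(rsid = s, n_hom_risk = cnt[1], n_het = cnt[2],
               n_hom_other = cnt[3],
               hwe_p = if (sum(cnt) > 0) hwe_exact_test(cnt[1], cnt[2], cnt[3]) else NA_real_)
  }))
  list(per_snp = per_snp, per_individual = per_ind,
       flagged_snps = names(per_snp)[per_snp < threshold], hwe = hwe)
}
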