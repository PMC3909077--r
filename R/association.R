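#' Per-SNP case-control association
#'
#' The additive genetic model: maximum-likelihood logistic regression of case
#' status on risk-allele dosage, one SNP at a time, unadjusted (the study
#' matches cases and controls on BMI rather than adjusting for it). Wald
#' standard errors from the observed information; 95% CI as
#' exp(beta +/- 1.96 se), mirroring the published tables' convention.
#'
#' @name association
NULL

.Z95 <- 1.96  # multiplier used for all printed-style 95% intervals

#' Additive-model logistic association for one SNP
#'
#' Individuals with missing dosage are dropped for that SNP. Fractional
#' (imputed expected) dosages enter the regression as-is. Monomorphic SNPs
#' and fits with (quasi-)separation are returned flagged non-estimable
#' rather than as errors, so a scan over a panel always completes.
#'
#' @param cohort a cohort.
#' @param rsid SNP to test.
#' @param z CI multiplier (default 1.96).
#' @return one-row data frame: `rsid`, `cohort`, `beta`, `se`, `or_`,
#'   `ci_low`, `ci_high`, `p`, `n_cases`, `n_controls`, `freq_cases`,
#'   `freq_controls`, `freq_overall`, `estimable`, `note`.
#' @export
additive_logistic <- function(cohort, rsid, z = .Z95) {
  if (!rsid %in% colnames(cohort$dosages)) .stopf("unknown SNP: %s", rsid)
  g <- cohort$dosages[, rsid]
  y <- cohort$status
  ok <- !is.na(g)
  g <- g[ok]; y <- y[ok]
  base <- data.frame(rsid = rsid, cohort = cohort$label,
                     beta = NA_real_, se = NA_real_, or_ = NA_real_,
                     ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
                     n_cases = sum(y == 1L), n_controls = sum(y == 0L),
                     freq_cases = mean(g[y == 1L]) / 2,
                     freq_controls = mean(g[y == 0L]) / 2,
                     freq_overall = mean(g) / 2,
                     estimable = FALSE, note = "", stringsAsFactors = FALSE)
  if (length(unique(y)) < 2) { base$note <- "single status class"; return(base) }
  if (stats::var(g) == 0) { base$note <- "monomorphic"; return(base) }
  # tight IRLS tolerance: the Wald SE must reproduce closed forms to ~1e-9
  fit <- suppressWarnings(stats::glm(y ~ g, family = stats::binomial(),
                                     control = stats::glm.control(epsilon = 1e-12,
                                                                  maxit = 100)))
  co <- summary(fit)$coefficients
  beta <- co["g", "Estimate"]; se <- co["g", "Std. Error"]
  if (!fit$converged || !is.finite(se) || se > 50 || abs(beta) > 25) {
    base$note <- "separation or non-convergence"
    return(base)
  }
  base$beta <- beta; base$se <- se
  base$or_ <- exp(beta)
  base$ci_low <- exp(beta - z * se); base$ci_high <- exp(beta + z * se)
  base$p <- 2 * stats::pnorm(-abs(beta / se))
  base$estimable <- TRUE
  base
}

#' Association scan over a panel
#'
#' @param cohort a cohort.
#' @param panel a [variant_panel]; defaults to the cohort's SNPs.
#' @param ... passed to [additive_logistic()].
#' @return data frame, one row per SNP.
#' @export
assoc_scan <- function(cohort, panel = NULL, ...) {
  snps <- if (is.null(panel)) colnames(cohort$dosages) else
    intersect(panel$rsid, colnames(cohort$dosages))
  do.call(rbind, lapply(snps, function(s) additive_logistic(cohort, s, ...)))
}

#' Risk-allele frequency
#'
#' (sum of dosages) / (2 x number of non-missing genotypes) within a group.
#'
#' @param cohort a cohort.
#' @param rsid SNP.
#' @param group `"all"`, `"case"` or `"control"`.
#' @return proportion in [0, 1].
#' @export
allele_freq <- function(cohort, rsid, group = c("all", "case", "control")) {
  group <- match.arg(group)
  g <- cohort$dosages[, rsid]
  g <- switch(group, all = g, case = g[cohort$status == 1L],
              control = g[cohort$status == 0L])
  g <- g[!is.na(g)]
  if (!length(g)) .stopf("no non-missing genotypes at %s in group '%s'", rsid, group)
  sum(g) / (2 * length(g))
}

#' Split a cohort at a BMI threshold
#'
#' BMI exactly at the threshold goes to the upper (at-or-above) stratum,
#' matching the study's obese stratum definition BMI >= 30 kg/m^2.
#' Individuals with missing BMI are dropped, with a message giving the count.
#'
#' @param cohort a cohort with BMI.
#' @param threshold kg/m^2 (default 30).
#' @return list with cohorts `below` and `at_or_above`.
#' @export
bmi_stratify <- function(cohort, threshold = 30) {
  if (is.null(cohort$bmi)) .stopf("cohort has no BMI")
  drop <- is.na(cohort$bmi)
  if (any(drop)) message(sprintf("dropping %d individuals with missing BMI", sum(drop)))
  lab <- cohort$label
  list(below = subset_cohort(cohort, !drop & cohort$bmi < threshold,
                             sprintf("%s_bmi_lt%g", lab, threshold)),
       at_or_above = subset_cohort(cohort, !drop & cohort$bmi >= threshold,
                                   sprintf("%s_bmi_ge%g", lab, threshold)))
}

#' Pearson chi-square test for an r x c contingency table
#'
#' Used for the case/control comparison of BMI-class prevalences
#' (normal weight / overweight / obese). No continuity correction,
#' df = (r-1)(c-1).
#'
#' @param table matrix of counts.
#' @return list with `statistic`, `df`, `p`.
#' @export
contingency_chisq <- function(table) {
  table <- as.matrix(table)
  exp_cnt <- outer(rowSums(table), colSums(table)) / sum(table)
  if (any(exp_cnt <= 0)) .stopf("all expected counts must be positive")
  ct <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p = unname(ct$p.value))
}

#' BMI-class prevalence table
#'
#' Counts and percentages of normal weight (BMI < 25), overweight
#' (25 <= BMI < 30) and obese (BMI >= 30) by case status.
#'
#' @param cohort a cohort with BMI.
#' @return list with the 2 x 3 count matrix `counts` (rows case/control),
#'   `percent` and the chi-square comparison `test`.
#' @export
bmi_class_table <- function(cohort) {
  if (is.null(cohort$bmi)) .stopf("cohort has no BMI")
  cls <- cut(cohort$bmi, c(-Inf, 25, 30, Inf), right = FALSE,
             labels = c("normal", "overweight", "obese"))
  counts <- table(factor(ifelse(cohort$status == 1L, "case", "control"),
                         levels = c("case", "control")), cls)
  counts <- unclass(counts)[, , drop = FALSE]
  list(counts = counts, percent = 100 * prop.table(counts, 1),
       test = contingency_chisq(counts))
}
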