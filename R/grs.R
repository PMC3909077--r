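#' Counted genetic risk score
#'
#' The unweighted allele-count score: every risk allele across the panel
#' contributes one point, so the maximum attainable score is 2 x 12 = 24 for
#' the packaged panel. Individuals genotyped for fewer than 90% of panel
#' SNPs (11 of 12) are excluded; remaining missing genotypes are replaced by
#' the SNP's mean observed dosage over the whole case-control set (cases and
#' controls pooled), so imputed scores are fractional. Scores are grouped
#' into the published bins (<8, 8-9, 10-11, 12-13, 14-15, 16-17, >=18 — the
#' top bin absorbs 18 itself so every score has a bin), per-bin odds ratios
#' against the reference bin use the Woolf 2x2 formula, and the overall
#' trend across bins is a tie-corrected Kruskal-Wallis rank test of bin by
#' case status.
#'
#' @name grs
NULL

.GRS_BREAKS <- c(-Inf, 8, 10, 12, 14, 16, 18, Inf)
.GRS_LABELS <- c("<8", "8 to 9", "10 to 11", "12 to 13", "14 to 15",
                 "16 to 17", ">=18")

#' Completeness filter for score inclusion
#'
#' Included iff the number of non-missing panel genotypes is at least
#' ceiling(min_prop x number of SNPs): with 12 SNPs and the default 0.9 this
#' is the published "at least 11 of 12" rule.
#'
#' @param dosages dosage matrix over the panel SNPs.
#' @param min_prop minimum genotyped proportion (default 0.9).
#' @return logical inclusion vector.
#' @export
completeness_filter <- function(dosages, min_prop = 0.9) {
  need <- ceiling(min_prop * ncol(dosages))
  rowSums(!is.na(dosages)) >= need
}

#' Mean-score imputation of missing genotypes
#'
#' Each missing dosage at SNP j is replaced by SNP j's mean observed dosage
#' over all supplied (already inclusion-filtered) individuals, cases and
#' controls pooled. Under Hardy-Weinberg the replacement approximates twice
#' the risk-allele frequency.
#'
#' @param dosages dosage matrix of included individuals.
#' @return completed numeric matrix (fractional where imputed).
#' @export
impute_mean_dosage <- function(dosages) {
  mu <- colMeans(dosages, na.rm = TRUE)
  if (anyNA(mu) || any(is.nan(mu)))
    .stopf("SNP(s) with zero observed genotypes: %s",
           paste(colnames(dosages)[is.na(mu) | is.nan(mu)], collapse = ", "))
  idx <- which(is.na(dosages), arr.ind = TRUE)
  if (nrow(idx)) dosages[idx] <- mu[idx[, "col"]]
  dosages
}

#' Allele-count scores
#'
#' Row sums of the completed dosage matrix; bounded by 2 x number of SNPs.
#'
#' @param completed dosage matrix with no missing values.
#' @return numeric score vector.
#' @export
compute_scores <- function(completed) {
  if (anyNA(completed)) .stopf("scores require a completed matrix (no NA)")
  rowSums(completed)
}

#' Assign scores to the published bins
#'
#' Fractional scores are binned by their integer part, preserving the
#' "number of alleles" reading; bins are <8, 8-9, 10-11, 12-13, 14-15,
#' 16-17 and >=18 (the top bin includes 18 so the binning is exhaustive).
#'
#' @param scores numeric scores.
#' @return ordered factor of bin labels.
#' @export
bin_scores <- function(scores) {
  cut(floor(scores), .GRS_BREAKS, labels = .GRS_LABELS, right = FALSE,
      ordered_result = TRUE)
}

#' Reference bin: the bin holding the mean control score
#'
#' @param scores numeric scores.
#' @param status 0/1 case indicator.
#' @return a bin label (character).
#' @export
select_reference_bin <- function(scores, status) {
  if (!any(status == 0L)) .stopf("no controls present")
  as.character(bin_scores(mean(scores[status == 0L])))
}

#' Per-bin odds ratios against the reference bin
#'
#' For a bin with a cases and b controls versus the reference bin's c cases
#' and d controls: OR = ad/(bc) with the Woolf 95% CI
#' exp(log OR +/- 1.96 sqrt(1/a + 1/b + 1/c + 1/d)). If any of the four
#' cells is zero, 0.5 is added to all four cells of that comparison only
#' (Haldane-Anscombe) and the row is flagged. The reference row carries the
#' counts with NA odds-ratio columns.
#'
#' @param bins factor of bin labels (from [bin_scores()]).
#' @param status 0/1 case indicator.
#' @param reference reference bin label (see [select_reference_bin()]).
#' @param z CI multiplier.
#' @return data frame with one row per bin: counts, percentages within
#'   cases/controls, `or_`, `ci_low`, `ci_high`, `reference`, `corrected`.
#' @export
bin_or_table <- function(bins, status, reference, z = .Z95) {
  stopifnot(length(bins) == length(status))
  lev <- levels(bins)
  if (!reference %in% lev) .stopf("unknown reference bin '%s'", reference)
  ca <- table(factor(bins[status == 1L], levels = lev))
  co <- table(factor(bins[status == 0L], levels = lev))
  cc <- as.numeric(ca[reference]); dd <- as.numeric(co[reference])
  if (cc < 1 || dd < 1) .stopf("reference bin must contain cases and controls")
  out <- data.frame(bin = lev, cases = as.numeric(ca), controls = as.numeric(co),
                    pct_cases = 100 * as.numeric(ca) / sum(ca),
                    pct_controls = 100 * as.numeric(co) / sum(co),
                    or_ = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                    reference = lev == reference, corrected = FALSE,
                    stringsAsFactors = FALSE)
  for (i in seq_along(lev)) {
    if (lev[i] == reference) next
    a <- out$cases[i]; b <- out$controls[i]; c2 <- cc; d2 <- dd
    if (min(a, b, c2, d2) == 0) {
      a <- a + 0.5; b <- b + 0.5; c2 <- c2 + 0.5; d2 <- d2 + 0.5
      out$corrected[i] <- TRUE
    }
    lor <- log(a * d2 / (b * c2))
    se <- sqrt(1 / a + 1 / b + 1 / c2 + 1 / d2)
    out$or_[i] <- exp(lor)
    out$ci_low[i] <- exp(lor - z * se)
    out$ci_high[i] <- exp(lor + z * se)
  }
  out
}

#' Trend across score bins
#'
#' Tie-corrected Kruskal-Wallis rank test of the bin ordinal grouped by case
#' status — with two groups this is the rank test of whether cases sit
#' systematically higher or lower in the score distribution.
#'
#' @param bins factor of bin labels.
#' @param status 0/1 case indicator.
#' @return list with `statistic`, `df`, `p`.
#' @export
grs_trend_test <- function(bins, status) {
  occ <- unique(bins[!is.na(bins)])
  if (length(occ) < 2) .stopf("trend test needs at least 2 occupied bins")
  kt <- stats::kruskal.test(as.integer(bins), factor(status))
  list(statistic = unname(kt$statistic), df = unname(kt$parameter),
       p = unname(kt$p.value))
}

#' Full genetic-risk-score analysis of a cohort
#'
#' Applies the completeness filter, mean-dosage imputation, scoring, binning
#' (reference = bin of the mean control score), per-bin odds ratios and the
#' trend test.
#'
#' @param cohort a cohort whose dosage columns are the panel SNPs.
#' @param min_prop completeness threshold (default 0.9).
#' @param reference optional fixed reference bin label.
#' @return list: `profiles` (per-individual id, n_genotyped, included,
#'   score, bin), `included` counts, `reference`, `bin_table`, `trend`.
#' @export
grs_analysis <- function(cohort, min_prop = 0.9, reference = NULL) {
  d <- cohort$dosages
  inc <- completeness_filter(d, min_prop)
  di <- impute_mean_dosage(d[inc, , drop = FALSE])
  scores <- compute_scores(di)
  status <- cohort$status[inc]
  bins <- bin_scores(scores)
  if (is.null(reference)) reference <- select_reference_bin(scores, status)
  profiles <- data.frame(id = cohort$ids, n_genotyped = rowSums(!is.na(d)),
                         included = inc, score = NA_real_, bin = NA_character_,
                         stringsAsFactors = FALSE)
  profiles$score[inc] <- scores
  profiles$bin[inc] <- as.character(bins)
  list(profiles = profiles,
       included = c(cases = sum(status == 1L), controls = sum(status == 0L),
                    excluded = sum(!inc)),
       reference = reference,
       bin_table = bin_or_table(bins, status, reference),
       trend = grs_trend_test(bins, status))
}
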