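#' Risk-variant panels
#'
#' A variant panel is a data frame with one row per biallelic SNP and columns
#' `rsid`, `chromosome`, `position`, `locus_name`, `risk_allele`,
#' `other_allele`, `overall_risk_freq` and optionally `info_quality`
#' (imputation info score) plus per-cohort frequency columns. The packaged
#' panel [bmi_panel()] carries the 12 BMI-associated loci (BDNF, FAIM2, ETV5,
#' FTO, GNPDA2, KCTD15, MC4R, MTCH2, NEGR1, SEC16B, SH2B1, TMEM18) with their
#' BMI-increasing risk alleles and risk-allele frequencies.
#'
#' @name variant_panel
NULL

.BASES <- c("A", "C", "G", "T")

validate_panel <- function(panel) {
  need <- c("rsid", "chromosome", "position", "locus_name",
            "risk_allele", "other_allele", "overall_risk_freq")
  miss <- setdiff(need, names(panel))
  if (length(miss)) .stopf("panel is missing columns: %s", paste(miss, collapse = ", "))
  if (anyDuplicated(panel$rsid)) .stopf("panel rsids must be unique")
  if (!all(panel$risk_allele %in% .BASES) || !all(panel$other_allele %in% .BASES))
    .stopf("alleles must be one of A, C, G, T")
  if (any(panel$risk_allele == panel$other_allele))
    .stopf("risk and other allele must differ")
  f <- panel$overall_risk_freq
  if (any(!is.finite(f) | f <= 0 | f >= 1))
    .stopf("overall_risk_freq must lie strictly in (0, 1)")
  class(panel) <- unique(c("variant_panel", class(panel)))
  panel
}

#' Read a risk-variant panel from TSV
#'
#' Tab-separated with a header row and optional `#` comment lines; columns as
#' described in [variant_panel].
#'
#' @param path path to the panel TSV.
#' @return a `variant_panel` data frame.
#' @export
read_panel <- function(path) {
  if (!file.exists(path)) .stopf("panel file not found: %s", path)
  panel <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  validate_panel(panel)
}

#' Write a risk-variant panel to TSV
#'
#' @param panel a `variant_panel`.
#' @param path output path.
#' @export
write_panel <- function(panel, path) {
  utils::write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' The packaged 12-SNP BMI risk-variant panel
#'
#' Lead SNPs of 12 BMI-associated loci replicated across ethnicities, with
#' their BMI-increasing risk alleles and overall risk-allele frequencies
#' (0.21 to 0.84). Non-risk alleles are the SNPs' standard biallelic partners;
#' they are not part of the published association table (see the fixture
#' header comments).
#'
#' @return a `variant_panel` of 12 rows.
#' @export
bmi_panel <- function() {
  read_panel(system.file("extdata", "bmi_panel.tsv", package = "pcosgrs",
                         mustWork = TRUE))
}

#' Identify strand-ambiguous SNPs in a panel
#'
#' A/T and C/G SNPs cannot be disambiguated across strand conventions; the
#' genotype readers warn about them.
#'
#' @param panel a `variant_panel`.
#' @return logical vector, one per SNP.
#' @export
strand_ambiguous <- function(panel) {
  pair <- paste(pmin(panel$risk_allele, panel$other_allele),
                pmax(panel$risk_allele, panel$other_allele))
  pair %in% c("A T", "C G")
}
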