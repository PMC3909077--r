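#' Rotterdam 2003 phenotype computations
#'
#' The diagnostic machinery used to define cases: the free androgen index
#' (FAI), the hirsutism threshold on the modified Ferriman-Gallwey score,
#' the polycystic ovarian morphology (PCOM) rule, and the 2-of-3 Rotterdam
#' classifier. Thresholds follow the criteria wording literally: FAI strictly
#' greater than 4.5, FG score of at least 8 (inclusive), at least 12
#' follicles (inclusive, max over the two ovaries), ovarian volume strictly
#' greater than 10 ml, cycle length strictly over 35 days or amenorrhea.
#'
#' @name phenotype
NULL

#' Free androgen index
#'
#' FAI = 100 x testosterone (nmol/L) / SHBG (nmol/L). Values exceeding 4.5
#' indicate biochemical hyperandrogenism.
#'
#' @param testosterone total testosterone in nmol/L, non-negative.
#' @param shbg sex hormone-binding globulin in nmol/L, strictly positive.
#' @return FAI (dimensionless), vectorized.
#' @export
compute_fai <- function(testosterone, shbg) {
  if (any(!is.finite(shbg)) || any(shbg <= 0)) .stopf("SHBG must be > 0 nmol/L")
  if (any(is.finite(testosterone) & testosterone < 0))
    .stopf("testosterone must be non-negative")
  100 * testosterone / shbg
}

.crit <- function(flag, missing_what) {
  # missing diagnostic inputs make the criterion FALSE, with a warning
  if (anyNA(flag)) {
    warning(sprintf("missing %s for %d record(s); criterion set to FALSE",
                    missing_what, sum(is.na(flag))))
    flag[is.na(flag)] <- FALSE
  }
  flag
}

#' Rotterdam 2003 classifier
#'
#' PCOS is diagnosed when at least two of three criteria hold:
#' oligo-/anovulation (cycle length over 35 days, or amenorrhea),
#' hyperandrogenism (FAI above 4.5 or modified Ferriman-Gallwey score of at
#' least 8), and PCOM (at least 12 follicles in one ovary or ovarian volume
#' above 10 ml). A record with `excluded_dx = TRUE` (Cushing's disease,
#' congenital adrenal hyperplasia or similar) is never classified PCOS.
#' Missing inputs make the affected criterion false, with a warning.
#'
#' @param records data frame with any of the columns `testosterone`, `shbg`,
#'   `fg_score`, `cycle_length_days`, `amenorrhea` (logical),
#'   `follicle_count_max`, `ovarian_volume_ml`, `excluded_dx` (logical).
#'   Absent columns are treated as all-missing.
#' @param fai_cutoff strict FAI threshold (default 4.5).
#' @param fg_cutoff inclusive FG-score threshold (default 8).
#' @param cycle_cutoff_days strict oligomenorrhea threshold (default 35).
#' @param follicle_cutoff inclusive follicle-count threshold (default 12).
#' @param volume_cutoff_ml strict ovarian-volume threshold (default 10).
#' @return data frame with `oligo_anovulation`, `hyperandrogenism`, `pcom`
#'   logical flags, `n_criteria` and `pcos`.
#' @export
classify_rotterdam <- function(records, fai_cutoff = 4.5, fg_cutoff = 8,
                               cycle_cutoff_days = 35, follicle_cutoff = 12,
                               volume_cutoff_ml = 10) {
  records <- as.data.frame(records)
  n <- nrow(records)
  col <- function(name) if (name %in% names(records)) records[[name]] else rep(NA, n)

  cycle <- col("cycle_length_days")
  amen <- col("amenorrhea")
  ovul <- (!is.na(cycle) & cycle > cycle_cutoff_days) | (!is.na(amen) & amen)
  ovul[is.na(cycle) & is.na(amen)] <- NA
  c1 <- .crit(ovul, "cycle length / amenorrhea")

  testo <- col("testosterone"); shbg <- col("shbg")
  fai <- ifelse(!is.na(testo) & !is.na(shbg) & shbg > 0,
                100 * testo / shbg, NA_real_)
  fg <- col("fg_score")
  ha <- (!is.na(fai) & fai > fai_cutoff) | (!is.na(fg) & fg >= fg_cutoff)
  ha[is.na(fai) & is.na(fg)] <- NA
  c2 <- .crit(ha, "androgen measures")

  fol <- col("follicle_count_max"); vol <- col("ovarian_volume_ml")
  pcom <- (!is.na(fol) & fol >= follicle_cutoff) | (!is.na(vol) & vol > volume_cutoff_ml)
  pcom[is.na(fol) & is.na(vol)] <- NA
  c3 <- .crit(pcom, "ultrasound measures")

  n_crit <- c1 + c2 + c3
  excl <- col("excluded_dx"); excl[is.na(excl)] <- FALSE
  data.frame(oligo_anovulation = c1, hyperandrogenism = c2, pcom = c3,
             n_criteria = n_crit, excluded_dx = as.logical(excl),
             pcos = n_crit >= 2 & !excl)
}

#' Read / write a phenotype TSV
#'
#' Tab-separated with a header and optional `#` comments; requires `id` and
#' `status` (1/2 PLINK coding or 0/1; normalized to 0 = control, 1 = case),
#' with optional `bmi` and the Rotterdam input columns of
#' [classify_rotterdam()].
#'
#' @param path file path.
#' @return data frame with normalized `status`.
#' @export
read_phenotype_tsv <- function(path) {
  if (!file.exists(path)) .stopf("phenotype file not found: %s", path)
  ph <- utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
  if (!all(c("id", "status") %in% names(ph)))
    .stopf("phenotype TSV needs 'id' and 'status' columns")
  s <- as.integer(ph$status)
  if (all(s %in% c(1L, 2L)) && any(s == 2L)) s <- s - 1L
  if (!all(s %in% c(0L, 1L))) .stopf("status must be coded 0/1 or 1/2")
  ph$status <- s
  ph$id <- as.character(ph$id)
  ph
}

#' @rdname read_phenotype_tsv
#' @param phenotypes data frame to write (status written as 0/1).
#' @export
write_phenotype_tsv <- function(phenotypes, path) {
  utils::write.table(phenotypes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(path)
}
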