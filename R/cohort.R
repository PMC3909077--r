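#' Case-control cohorts
#'
#' A `cohort` bundles a dosage matrix (individuals x SNPs; entries count the
#' panel's risk allele, in `[0, 2]`, fractional for imputed input, `NA` for
#' missing), a case indicator (1 = case, 0 = control), an optional BMI vector
#' and a label. Dosages are always oriented to the panel's risk allele, never
#' to whichever allele a file format happens to call A1.
#'
#' @param ids character individual identifiers.
#' @param dosages numeric matrix, rows = individuals, columns named by rsid.
#' @param status integer/logical case indicator (1 case, 0 control).
#' @param bmi numeric BMI in kg/m^2, or NULL.
#' @param label cohort label, e.g. `"UK"`.
#' @return an object of class `cohort`.
#' @export
new_cohort <- function(ids, dosages, status, bmi = NULL, label = "cohort") {
  dosages <- as.matrix(dosages)
  if (length(ids) != nrow(dosages)) .stopf("length(ids) != nrow(dosages)")
  if (length(status) != nrow(dosages)) .stopf("status length != nrow(dosages)")
  status <- as.integer(status)
  if (!all(status %in% c(0L, 1L))) .stopf("status must be coded 0 (control) / 1 (case)")
  if (!is.null(bmi) && length(bmi) != nrow(dosages)) .stopf("bmi length mismatch")
  d <- dosages[!is.na(dosages)]
  if (length(d) && (min(d) < 0 || max(d) > 2)) .stopf("dosages must lie in [0, 2]")
  if (is.null(colnames(dosages))) .stopf("dosage columns must be named by rsid")
  rownames(dosages) <- ids
  structure(list(ids = as.character(ids), dosages = dosages,
                 status = status, bmi = bmi, label = label),
            class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf("<cohort '%s'> %d cases / %d controls, %d SNPs, %.1f%% missing\n",
              x$label, sum(x$status == 1L), sum(x$status == 0L),
              ncol(x$dosages), 100 * mean(is.na(x$dosages))))
  invisible(x)
}

#' @export
dim.cohort <- function(x) dim(x$dosages)

#' Number of cases and controls in a cohort
#' @param cohort a `cohort`.
#' @return named integer vector with elements `cases` and `controls`.
#' @export
cohort_counts <- function(cohort) {
  c(cases = sum(cohort$status == 1L), controls = sum(cohort$status == 0L))
}

#' Subset a cohort by individuals
#' @param cohort a `cohort`.
#' @param keep logical or integer index over individuals.
#' @param label optional new label.
#' @return a `cohort`.
#' @export
subset_cohort <- function(cohort, keep, label = cohort$label) {
  new_cohort(cohort$ids[keep], cohort$dosages[keep, , drop = FALSE],
             cohort$status[keep],
             if (!is.null(cohort$bmi)) cohort$bmi[keep], label)
}
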