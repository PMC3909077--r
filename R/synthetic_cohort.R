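#' Synthetic case-control cohort generator
#'
#' Generates cohorts with the statistical structure the downstream analysis
#' assumes: independent biallelic SNPs in Hardy-Weinberg proportions at the
#' panel's risk-allele frequencies, case status from a logistic-additive
#' disease model on allele count, entry-wise genotype missingness, BMI drawn
#' log-normal, and Rotterdam-style phenotype measures consistent with case
#' status. Defaults mirror the study conditions: case-control sets of
#' 563/791 and 510/2720, ~5\% missingness (genotyping success above 95\%),
#' per-allele odds ratios of 1.0 (the null the study could not reject), and
#' BMI with median near 26.3 and IQR near 24-29 kg/m^2, independent of
#' genotype.
#'
#' @name synthetic_cohort
NULL

#' Simulation specification
#'
#' @param n_cases,n_controls target cohort sizes (the study's sets were
#'   563/791 and 510/2720).
#' @param panel a [variant_panel] (default [bmi_panel()]).
#' @param per_allele_or named vector of per-risk-allele odds ratios, one per
#'   panel SNP; a single unnamed value is recycled. Default 1 (no effect).
#' @param baseline_case_odds disease odds for a carrier of zero risk alleles.
#' @param missing_rate entry-wise genotype missingness probability in [0, 1).
#' @param seed global seed; stage seeds derive from it via [derive_seed()].
#' @return a `sim_spec` list.
#' @export
sim_spec <- function(n_cases = 563, n_controls = 791, panel = bmi_panel(),
                     per_allele_or = 1, baseline_case_odds = 0.15,
                     missing_rate = 0.05, seed = 1L) {
  panel <- validate_panel(panel)
  if (n_cases < 1 || n_controls < 1) .stopf("need at least 1 case and 1 control")
  if (length(per_allele_or) == 1 && is.null(names(per_allele_or)))
    per_allele_or <- stats::setNames(rep(per_allele_or, nrow(panel)), panel$rsid)
  miss <- setdiff(panel$rsid, names(per_allele_or))
  if (length(miss)) .stopf("per_allele_or missing for: %s", paste(miss, collapse = ", "))
  if (any(per_allele_or <= 0)) .stopf("per-allele odds ratios must be positive")
  if (baseline_case_odds <= 0) .stopf("baseline_case_odds must be positive")
  .check_prop(missing_rate, "missing_rate", open_right = TRUE)
  structure(list(n_cases = as.integer(n_cases), n_controls = as.integer(n_controls),
                 panel = panel, per_allele_or = per_allele_or[panel$rsid],
                 baseline_case_odds = baseline_case_odds,
                 missing_rate = missing_rate, seed = as.integer(seed)),
            class = "sim_spec")
}

#' Draw Hardy-Weinberg genotypes
#'
#' Per SNP with risk-allele frequency p, dosages are drawn with
#' P(2) = p^2, P(1) = 2p(1-p), P(0) = (1-p)^2, independently across SNPs
#' (the panel loci are treated as unlinked).
#'
#' @param panel a panel data frame with `rsid` and `overall_risk_freq`
#'   columns; frequencies may include the degenerate 0 and 1.
#' @param n number of individuals.
#' @param seed RNG seed.
#' @return n x SNP integer dosage matrix with values in \{0, 1, 2\}.
#' @export
simulate_genotypes <- function(panel, n, seed) {
  p <- panel$overall_risk_freq
  if (any(!is.finite(p) | p < 0 | p > 1))
    .stopf("risk-allele frequencies must lie in [0, 1]")
  set.seed(as.integer(seed))
  d <- vapply(p, function(f) stats::rbinom(n, 2L, f), integer(n))
  if (n == 1L) d <- matrix(d, nrow = 1L)
  colnames(d) <- panel$rsid
  d
}

#' Case probabilities and status under the logistic-additive disease model
#'
#' P(case | g) = logistic(log baseline odds + sum_j g_j log OR_j): each risk
#' allele multiplies the disease odds by its per-allele odds ratio, matching
#' the additive model the association stage fits.
#'
#' @param dosages dosage matrix (no missing values).
#' @param spec a [sim_spec()].
#' @return `case_probability`: vector of P(case); `assign_status`: a 0/1
#'   draw from those probabilities.
#' @export
case_probability <- function(dosages, spec) {
  lo <- log(spec$baseline_case_odds) +
    as.vector(dosages[, names(spec$per_allele_or), drop = FALSE] %*%
                log(spec$per_allele_or))
  stats::plogis(lo)
}

#' @rdname case_probability
#' @param seed RNG seed.
#' @export
assign_status <- function(dosages, spec, seed = derive_seed(spec$seed, "status")) {
  set.seed(as.integer(seed))
  as.integer(stats::runif(nrow(dosages)) < case_probability(dosages, spec))
}

#' Entry-wise genotype missingness
#'
#' Each entry is independently set missing with the given probability,
#' emulating assay dropout.
#'
#' @param dosages dosage matrix.
#' @param rate missingness probability in [0, 1).
#' @param seed RNG seed.
#' @return the matrix with `NA` entries.
#' @export
apply_missingness <- function(dosages, rate, seed) {
  .check_prop(rate, "rate", open_right = TRUE)
  if (rate == 0) return(dosages)
  set.seed(as.integer(seed))
  drop <- matrix(stats::runif(length(dosages)) < rate, nrow(dosages))
  dosages[drop] <- NA
  dosages
}

#' Log-normal BMI
#'
#' Median ~26.3 kg/m^2 and IQR ~24-29 (the Dutch controls' distribution),
#' independent of genotype.
#'
#' @param n number of individuals.
#' @param seed RNG seed.
#' @param meanlog,sdlog log-normal parameters; defaults reproduce the
#'   median/IQR above.
#' @return numeric BMI vector.
#' @export
simulate_bmi <- function(n, seed, meanlog = log(26.3), sdlog = 0.1403) {
  set.seed(as.integer(seed))
  stats::rlnorm(n, meanlog, sdlog)
}

#' Rotterdam-style phenotype measures consistent with case status
#'
#' Cases are given measure sets satisfying at least two of the three
#' Rotterdam criteria, controls at most one, by rejection; quantitative
#' values (testosterone/SHBG, FG score, cycle length, follicle count,
#' ovarian volume) are drawn on either side of the diagnostic thresholds
#' accordingly. The marginal criterion frequencies among cases
#' (oligo-/anovulation 0.80, hyperandrogenism 0.70, PCOM 0.75) are ordinary
#' clinic proportions for Rotterdam-diagnosed PCOS; among controls each
#' criterion is uncommon (0.08, 0.08, 0.20).
#'
#' @param status 0/1 case indicator.
#' @param seed RNG seed.
#' @return data frame of classifier inputs, one row per individual.
#' @export
simulate_phenotypes <- function(status, seed) {
  set.seed(as.integer(seed))
  n <- length(status)
  p_case <- c(0.80, 0.70, 0.75); p_ctrl <- c(0.08, 0.08, 0.20)
  flags <- matrix(FALSE, n, 3)
  for (i in seq_len(n)) {
    p <- if (status[i] == 1L) p_case else p_ctrl
    repeat {
      f <- stats::runif(3) < p
      ok <- if (status[i] == 1L) sum(f) >= 2 else sum(f) < 2
      if (ok) break
    }
    flags[i, ] <- f
  }
  oligo <- flags[, 1]; ha <- flags[, 2]; pcom <- flags[, 3]
  amen <- oligo & stats::runif(n) < 0.15
  cycle <- ifelse(oligo, round(stats::runif(n, 36, 120)), round(stats::runif(n, 25, 34)))
  cycle[amen] <- NA
  shbg <- stats::rlnorm(n, log(45), 0.35)
  fai <- ifelse(ha, stats::runif(n, 5, 15), stats::runif(n, 0.5, 4.0))
  fg <- ifelse(ha & stats::runif(n) < 0.5,
               round(stats::runif(n, 8, 20)), round(stats::runif(n, 0, 5)))
  fol <- ifelse(pcom, round(stats::runif(n, 12, 40)), round(stats::runif(n, 2, 9)))
  vol <- ifelse(pcom, stats::runif(n, 8, 18), stats::runif(n, 3, 9))
  data.frame(cycle_length_days = cycle, amenorrhea = amen,
             testosterone = fai * shbg / 100, shbg = shbg, fg_score = fg,
             follicle_count_max = fol, ovarian_volume_ml = vol,
             excluded_dx = FALSE)
}

#' Simulate a full case-control cohort
#'
#' Draws genotype/status pairs from the Hardy-Weinberg + logistic-additive
#' model and keeps them until exactly `n_cases` cases and `n_controls`
#' controls are collected (rejection sampling, capped at 1e7 draws so an
#' unreachable quota fails instead of hanging), then applies genotype
#' missingness and attaches BMI.
#'
#' @param spec a [sim_spec()].
#' @param label cohort label.
#' @param max_draws rejection-sampling cap.
#' @return a cohort.
#' @export
simulate_cohort <- function(spec, label = "sim", max_draws = 1e7) {
  stopifnot(inherits(spec, "sim_spec"))
  set.seed(derive_seed(spec$seed, "genotypes"))
  n_snp <- nrow(spec$panel)
  need_ca <- spec$n_cases; need_co <- spec$n_controls
  keep_d <- matrix(NA_real_, need_ca + need_co, n_snp,
                   dimnames = list(NULL, spec$panel$rsid))
  keep_s <- integer(need_ca + need_co)
  got_ca <- 0L; got_co <- 0L; drawn <- 0
  batch <- max(1000L, need_ca + need_co)
  while ((got_ca < need_ca || got_co < need_co)) {
    if (drawn >= max_draws)
      .stopf("could not reach %d cases / %d controls within %g draws",
             need_ca, need_co, max_draws)
    b <- min(batch, max_draws - drawn); drawn <- drawn + b
    g <- vapply(spec$panel$overall_risk_freq,
                function(f) stats::rbinom(b, 2L, f), integer(b))
    if (b == 1L) g <- matrix(g, nrow = 1L)
    colnames(g) <- spec$panel$rsid
    s <- as.integer(stats::runif(b) < case_probability(g, spec))
    for (cls in c(1L, 0L)) {
      want <- if (cls == 1L) need_ca - got_ca else need_co - got_co
      if (want <= 0) next
      idx <- which(s == cls)[seq_len(min(want, sum(s == cls)))]
      if (!length(idx)) next
      at <- (got_ca + got_co) + seq_along(idx)
      keep_d[at, ] <- g[idx, , drop = FALSE]
      keep_s[at] <- cls
      if (cls == 1L) got_ca <- got_ca + length(idx) else got_co <- got_co + length(idx)
    }
  }
  d <- apply_missingness(keep_d, spec$missing_rate,
                         derive_seed(spec$seed, "missingness"))
  bmi <- simulate_bmi(nrow(d), derive_seed(spec$seed, "bmi"))
  new_cohort(sprintf("%s_%05d", label, seq_len(nrow(d))), d, keep_s, bmi, label)
}
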