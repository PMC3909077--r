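#' Case-control genetic power
#'
#' Analytic power of the 1-df allelic (trend-type) test under a
#' multiplicative per-allele model, as used to size candidate-SNP
#' case-control studies. With population-based controls the control
#' risk-allele frequency equals the population frequency; with known
#' unaffected controls it is depleted of risk alleles according to the
#' disease prevalence. Power comes from the two-proportion z-test on allele
#' counts with pooled variance under the null and unpooled variance under
#' the alternative.
#'
#' @param freq population risk-allele frequency in (0, 1).
#' @param or_ per-allele (allelic) odds ratio.
#' @param alpha two-sided significance level.
#' @param n_cases,n_controls numbers of individuals.
#' @param control_type `"population"` (default; the study design) or
#'   `"unaffected"`.
#' @param prevalence disease prevalence; needed only for unaffected
#'   controls.
#' @return power in (0, 1).
#' @export
case_control_power <- function(freq, or_, alpha = 0.05, n_cases, n_controls,
                               control_type = c("population", "unaffected"),
                               prevalence = NULL) {
  control_type <- match.arg(control_type)
  .check_prop(freq, "freq", open_left = TRUE, open_right = TRUE)
  .check_prop(alpha, "alpha", open_left = TRUE, open_right = TRUE)
  if (or_ <= 0) .stopf("odds ratio must be positive")
  if (n_cases < 1 || n_controls < 1) .stopf("need positive sample sizes")

  # case allele frequency under the multiplicative allelic model
  p_case <- freq * or_ / (freq * or_ + (1 - freq))
  p_ctrl <- if (control_type == "population") freq else {
    if (is.null(prevalence)) .stopf("unaffected controls need a prevalence")
    .check_prop(prevalence, "prevalence", open_left = TRUE, open_right = TRUE)
    # unaffected controls: allele frequency among non-cases
    (freq - prevalence * p_case) / (1 - prevalence)
  }

  m1 <- 2 * n_cases; m2 <- 2 * n_controls  # allele counts
  diff <- p_case - p_ctrl
  pbar <- (m1 * p_case + m2 * p_ctrl) / (m1 + m2)
  sd0 <- sqrt(pbar * (1 - pbar) * (1 / m1 + 1 / m2))          # pooled, null
  sd1 <- sqrt(p_case * (1 - p_case) / m1 + p_ctrl * (1 - p_ctrl) / m2)
  zc <- stats::qnorm(1 - alpha / 2)
  stats::pnorm((diff - zc * sd0) / sd1) + stats::pnorm((-diff - zc * sd0) / sd1)
}

#' Empirical power by simulation
#'
#' Simulates single-SNP case-control datasets of the requested size from the
#' Hardy-Weinberg + logistic-additive generator and counts Wald rejections
#' of the additive-model logistic fit — an independent check on
#' [case_control_power()].
#'
#' @inheritParams case_control_power
#' @param n_reps number of replicate datasets.
#' @param seed RNG seed.
#' @return list with `power` (rejection proportion), `n_reps` and the
#'   Monte-Carlo `se`.
#' @export
estimate_power_empirical <- function(freq, or_, alpha = 0.05, n_cases,
                                     n_controls, n_reps = 2000, seed = 1L) {
  panel <- data.frame(rsid = "snp", chromosome = "1", position = 1L,
                      locus_name = "SIM", risk_allele = "A", other_allele = "G",
                      overall_risk_freq = freq, stringsAsFactors = FALSE)
  spec <- sim_spec(n_cases, n_controls, validate_panel(panel),
                   per_allele_or = c(snp = or_), missing_rate = 0, seed = seed)
  set.seed(as.integer(seed))
  rej <- logical(n_reps)
  for (r in seq_len(n_reps)) {
    coh <- .simulate_quota_fast(spec)
    fit <- additive_logistic(coh, "snp")
    rej[r] <- fit$estimable && fit$p < alpha
  }
  list(power = mean(rej), n_reps = n_reps,
       se = sqrt(mean(rej) * (1 - mean(rej)) / n_reps))
}

# quota sampler that reuses the ambient RNG stream (no per-call reseeding),
# for replicate loops
.simulate_quota_fast <- function(spec, max_draws = 1e7) {
  need_ca <- spec$n_cases; need_co <- spec$n_controls
  g_keep <- numeric(0); s_keep <- integer(0); drawn <- 0
  p <- spec$panel$overall_risk_freq
  while (length(s_keep) < need_ca + need_co) {
    if (drawn >= max_draws) .stopf("unreachable case/control quota")
    b <- min(4 * (need_ca + need_co), max_draws - drawn); drawn <- drawn + b
    g <- stats::rbinom(b, 2L, p)
    pr <- stats::plogis(log(spec$baseline_case_odds) + g * log(spec$per_allele_or[1]))
    s <- as.integer(stats::runif(b) < pr)
    ca <- which(s == 1L)[seq_len(min(need_ca - sum(s_keep == 1L), sum(s == 1L)))]
    co <- which(s == 0L)[seq_len(min(need_co - sum(s_keep == 0L), sum(s == 0L)))]
    idx <- c(ca[!is.na(ca)], co[!is.na(co)])
    g_keep <- c(g_keep, g[idx]); s_keep <- c(s_keep, s[idx])
  }
  d <- matrix(g_keep, ncol = 1, dimnames = list(NULL, "snp"))
  new_cohort(as.character(seq_along(s_keep)), d, s_keep, label = "powersim")
}
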