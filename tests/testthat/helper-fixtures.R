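# Small in-code fixtures and independent oracles shared across test files.

# two-SNP toy panel (rs9939609 is A/T, i.e. strand-ambiguous)
toy_panel <- function() {
  validate_panel(data.frame(
    rsid = c("rs9939609", "rs17782313"),
    chromosome = c("16", "18"),
    position = c(52378028L, 56002077L),
    locus_name = c("FTO", "MC4R"),
    risk_allele = c("A", "C"),
    other_allele = c("T", "T"),
    overall_risk_freq = c(0.40, 0.25),
    stringsAsFactors = FALSE))
}

single_snp_panel <- function(freq, rsid = "snp1") {
  validate_panel(data.frame(
    rsid = rsid, chromosome = "1", position = 1L, locus_name = "SIM",
    risk_allele = "A", other_allele = "G", overall_risk_freq = freq,
    stringsAsFactors = FALSE))
}

# deterministic toy cohort: dosages chosen by hand, half cases
toy_cohort <- function() {
  d <- matrix(c(2, 1, 0, 1, 2, 0,
                1, 1, 0, 2, 0, 1), ncol = 2,
              dimnames = list(NULL, c("rs9939609", "rs17782313")))
  new_cohort(sprintf("id%02d", 1:6), d, c(1, 1, 1, 0, 0, 0),
             bmi = c(31, 24, 28, 30, 22, 35), label = "toy")
}

# a cohort that collapses to the 2x2 table (a, b, c, d):
# a cases / b controls with dosage 1, c cases / d controls with dosage 0
cohort_from_2x2 <- function(a, b, c, d, rsid = "snp1") {
  g <- c(rep(1, a + b), rep(0, c + d))
  y <- c(rep(1, a), rep(0, b), rep(1, c), rep(0, d))
  m <- matrix(g, ncol = 1, dimnames = list(NULL, rsid))
  new_cohort(as.character(seq_along(y)), m, y, label = "tab")
}

# Woolf closed form on a 2x2 (exposure x status) table
woolf_or <- function(a, b, c, d, z = 1.96) {
  lor <- log(a * d / (b * c))
  se <- sqrt(1 / a + 1 / b + 1 / c + 1 / d)
  list(beta = lor, se = se, or_ = exp(lor),
       ci_low = exp(lor - z * se), ci_high = exp(lor + z * se))
}

# Brute-force Hardy-Weinberg exact p-value: enumerate every heterozygote
# count compatible with the allele counts and sum the probabilities no
# larger than the observed one. Uses direct choose() products, a different
# arithmetic path from the implementation's lgamma form.
hwe_oracle <- function(n_hom_risk, n_het, n_hom_other) {
  n <- n_hom_risk + n_het + n_hom_other
  n_rare <- min(2 * n_hom_risk + n_het, 2 * n_hom_other + n_het)
  if (n_rare == 0) return(1.0)
  hets <- seq(n_rare %% 2, n_rare, by = 2)
  pr <- sapply(hets, function(h) {
    hom_r <- (n_rare - h) / 2
    choose(n, hom_r) * choose(n - hom_r, h) * 2^h / choose(2 * n, n_rare)
  })
  p_obs <- pr[match(n_het, hets)]
  sum(pr[pr <= p_obs * (1 + 1e-9)])
}

# Tie-corrected Kruskal-Wallis computed from first principles (ranks by hand)
kw_oracle <- function(x, g) {
  r <- rank(x)
  n <- length(x)
  h <- 12 / (n * (n + 1)) *
    sum(tapply(r, g, function(ri) sum(ri)^2 / length(ri))) - 3 * (n + 1)
  ties <- table(x)
  correction <- 1 - sum(ties^3 - ties) / (n^3 - n)
  h / correction
}
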