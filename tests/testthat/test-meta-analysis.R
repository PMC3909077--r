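test_that("se_from_ci inverts the exp(beta +/- 1.96 se) convention", {
  est <- se_from_ci(1.05, 0.90, 1.23)
  expect_equal(est$se, (log(1.23) - log(0.90)) / 3.92, tolerance = 1e-12)
  expect_equal(est$se, 0.0797, tolerance = 1e-3)
  sym <- se_from_ci(exp(1), 1, exp(2))
  expect_equal(sym$se, 2 / 3.92, tolerance = 1e-12)
  expect_equal(sym$asymmetry, 0, tolerance = 1e-12)
  expect_error(se_from_ci(1.0, 1.0, 1.0), "degenerate")
  expect_error(se_from_ci(1.0, -1, 2), "positive")
  expect_error(se_from_ci(0.8, 0.9, 1.2), "ci_low <= or_")
})

test_that("se_from_ci round-trips a constructed interval to 1e-12", {
  set.seed(81)
  for (i in 1:25) {
    beta <- runif(1, -1, 1); se <- runif(1, 0.01, 0.5)
    est <- se_from_ci(exp(beta), exp(beta - 1.96 * se), exp(beta + 1.96 * se))
    expect_equal(est$se, se, tolerance = 1e-12)
    expect_equal(est$beta, beta, tolerance = 1e-12)
  }
})

test_that("fixed-effect pooling reproduces published combined odds ratios", {
  # FAIM2 locus: UK 1.05 (0.90-1.23) + NL 1.02 (0.89-1.17) -> 1.03 (0.93-1.14)
  uk <- se_from_ci(1.05, 0.90, 1.23); nl <- se_from_ci(1.02, 0.89, 1.17)
  fe <- fixed_effect(c(uk$beta, nl$beta), c(uk$se, nl$se))
  expect_equal(round(fe$or_pooled, 2), 1.03)
  expect_equal(round(fe$ci_low, 2), 0.93)
  expect_equal(round(fe$ci_high, 2), 1.14)
  expect_identical(fe$model, "fixed")
  expect_equal(fe$tau2, 0)
})

test_that("identical and equal-precision estimates pool as expected", {
  two <- fixed_effect(c(0.2, 0.2), c(0.1, 0.1))
  expect_equal(two$beta_pooled, 0.2)
  expect_equal(two$q_stat, 0)
  expect_equal(two$i2, 0)
  eq <- fixed_effect(c(0.1, 0.3, 0.5), c(0.2, 0.2, 0.2))
  expect_equal(eq$beta_pooled, 0.3)  # equal weights -> arithmetic mean
  expect_error(fixed_effect(0.2, 0.1), "at least 2")
})

test_that("DerSimonian-Laird pooling reproduces the published SH2B1 estimate", {
  uk <- se_from_ci(1.04, 0.88, 1.22); nl <- se_from_ci(0.79, 0.69, 0.90)
  dl <- dl_random(c(uk$beta, nl$beta), c(uk$se, nl$se))
  expect_equal(round(dl$or_pooled, 2), 0.90)
  expect_gt(dl$tau2, 0)
  expect_identical(dl$model, "random")
})

test_that("DL truncates to the fixed-effect result when Q <= k - 1", {
  beta <- c(0.10, 0.12, 0.11); se <- c(0.3, 0.3, 0.3)
  fe <- fixed_effect(beta, se); dl <- dl_random(beta, se)
  expect_equal(dl$tau2, 0)
  expect_equal(dl$beta_pooled, fe$beta_pooled)
  expect_equal(dl$se_pooled, fe$se_pooled)
})

test_that("with dominant tau2 the DL weights tend to equality", {
  # tiny within-study variances + discrepant effects: pooled -> plain mean
  beta <- c(-0.5, 0.9); se <- c(0.001, 0.002)
  dl <- dl_random(beta, se)
  expect_equal(dl$beta_pooled, mean(beta), tolerance = 1e-4)
})

test_that("the I2 rule switches models strictly above 25%", {
  uk <- se_from_ci(1.04, 0.88, 1.22); nl <- se_from_ci(0.79, 0.69, 0.90)
  sel <- select_model(c(uk$beta, nl$beta), c(uk$se, nl$se))
  expect_identical(sel$model, "random")
  expect_equal(sel$i2, 0.85, tolerance = 0.01)
  expect_identical(select_model(c(0.2, 0.2), c(0.1, 0.1))$model, "fixed")
  # constructed I2 of exactly 0.25 (Q = 4/3 on 1 df) stays fixed
  d <- sqrt(8 / 3)
  at <- select_model(c(0, d), c(1, 1))
  expect_equal(at$i2, 0.25, tolerance = 1e-12)
  expect_identical(at$model, "fixed")
})

test_that("pooled variance never exceeds the best component and DL is wider", {
  set.seed(91)
  for (i in 1:20) {
    k <- sample(2:5, 1)
    beta <- rnorm(k, 0, 0.4); se <- runif(k, 0.05, 0.4)
    fe <- fixed_effect(beta, se); dl <- dl_random(beta, se)
    expect_lte(fe$se_pooled^2, min(se^2) + 1e-12)
    expect_gte(dl$ci_high - dl$ci_low, fe$ci_high - fe$ci_low - 1e-12)
    perm <- sample(k)
    fp <- fixed_effect(beta[perm], se[perm])
    expect_equal(fp$beta_pooled, fe$beta_pooled, tolerance = 1e-12)
    expect_equal(fp$q_stat, fe$q_stat, tolerance = 1e-12)
  }
})

test_that("fixed and DL estimators agree with metafor", {
  skip_if_not_installed("metafor")
  set.seed(101)
  for (i in 1:10) {
    k <- sample(2:6, 1)
    beta <- rnorm(k, 0.1, 0.5); se <- runif(k, 0.05, 0.5)
    fe <- fixed_effect(beta, se)
    rf <- metafor::rma(yi = beta, sei = se, method = "FE")
    expect_equal(fe$beta_pooled, as.numeric(rf$beta), tolerance = 1e-8)
    expect_equal(fe$se_pooled, rf$se, tolerance = 1e-8)
    expect_equal(fe$q_stat, rf$QE, tolerance = 1e-8)
    dl <- dl_random(beta, se)
    rd <- metafor::rma(yi = beta, sei = se, method = "DL")
    expect_equal(dl$beta_pooled, as.numeric(rd$beta), tolerance = 1e-8)
    expect_equal(dl$se_pooled, rd$se, tolerance = 1e-8)
    expect_equal(dl$tau2, rd$tau2, tolerance = 1e-8)
  }
})

test_that("meta_from_or_table pools each SNP's rows and keeps input order", {
  tab <- data.frame(rsid = c("a", "a", "b", "b"),
                    cohort = c("UK", "NL", "UK", "NL"),
                    or = c(1.05, 1.02, 1.04, 0.79),
                    ci_low = c(0.90, 0.89, 0.88, 0.69),
                    ci_high = c(1.23, 1.17, 1.22, 0.90))
  out <- meta_from_or_table(tab)
  expect_equal(out$rsid, c("a", "b"))
  expect_identical(out$model, c("fixed", "random"))
  expect_equal(round(out$or_pooled, 2), c(1.03, 0.90))
})
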