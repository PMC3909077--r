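test_that("completeness filter implements the 11-of-12 rule", {
  d <- matrix(1, 3, 12, dimnames = list(NULL, paste0("s", 1:12)))
  d[2, 1] <- NA            # 11 of 12
  d[3, 1:2] <- NA          # 10 of 12
  expect_equal(completeness_filter(d), c(TRUE, TRUE, FALSE))
  expect_equal(completeness_filter(d, min_prop = 1), c(TRUE, FALSE, FALSE))
})

test_that("missing dosages are replaced by the SNP's pooled mean", {
  d <- matrix(c(0, 1, 2, 1, NA), 5, 1, dimnames = list(NULL, "s"))
  expect_equal(unname(impute_mean_dosage(d)[5, 1]), 1.0)
  full <- matrix(c(0, 1, 2, 2), 2, 2, dimnames = list(NULL, c("a", "b")))
  expect_identical(impute_mean_dosage(full), full)
  allna <- matrix(NA_real_, 3, 1, dimnames = list(NULL, "s"))
  expect_error(impute_mean_dosage(allna), "zero observed")
})

test_that("imputation under HWE approximates twice the allele frequency", {
  g <- simulate_genotypes(single_snp_panel(0.3), 20000, seed = 111)
  g <- apply_missingness(g, 0.05, seed = 112)
  storage.mode(g) <- "double"
  filled <- impute_mean_dosage(g)
  imputed <- filled[is.na(g)]
  expect_lt(abs(imputed[1] - 2 * 0.3), 0.02)
})

test_that("scores are row sums bounded by twice the SNP count", {
  m <- matrix(2, 2, 12, dimnames = list(NULL, paste0("s", 1:12)))
  expect_equal(compute_scores(m), c(24, 24))
  expect_equal(compute_scores(m * 0), c(0, 0))
  expect_equal(unname(compute_scores(matrix(1, 1, 12))), 12)
  m[1, 1] <- NA
  expect_error(compute_scores(m), "completed")
})

test_that("score binning matches the published bins and is exhaustive", {
  expect_equal(as.character(bin_scores(7.6)), "<8")
  expect_equal(as.character(bin_scores(13.0)), "12 to 13")
  expect_equal(as.character(bin_scores(18)), ">=18")  # top bin absorbs 18
  expect_equal(as.character(bin_scores(c(0, 7.99, 8, 9.7, 10, 11.5, 12, 14, 16, 17.9, 19, 24))),
               c("<8", "<8", "8 to 9", "8 to 9", "10 to 11", "10 to 11",
                 "12 to 13", "14 to 15", "16 to 17", "16 to 17", ">=18", ">=18"))
  s <- runif(500, 0, 24)
  expect_false(anyNA(bin_scores(s)))  # every score gets exactly one bin
})

test_that("the reference bin holds the mean control score", {
  scores <- c(10, 14, 12.2, 12.6)   # controls mean 12.4
  status <- c(1L, 1L, 0L, 0L)
  expect_equal(select_reference_bin(scores, status), "12 to 13")
  expect_equal(select_reference_bin(c(9.8, 10.0), c(1L, 0L)), "10 to 11")
  expect_equal(select_reference_bin(c(9.9, 9.9), c(0L, 0L)), "8 to 9")
  expect_error(select_reference_bin(scores, c(1L, 1L, 1L, 1L)), "no controls")
})

test_that("per-bin odds ratios reproduce the published score-bin table", {
  # reconstruct bins from the printed combined/NL counts
  mk <- function(counts_cases, counts_controls) {
    lev <- c("<8", "8 to 9", "10 to 11", "12 to 13", "14 to 15", "16 to 17", ">=18")
    bins <- factor(c(rep(lev, counts_cases), rep(lev, counts_controls)),
                   levels = lev, ordered = TRUE)
    status <- rep(c(1L, 0L), c(sum(counts_cases), sum(counts_controls)))
    list(bins = bins, status = status)
  }
  comb <- mk(c(11, 86, 257, 319, 254, 72, 15), c(45, 269, 788, 1176, 812, 268, 42))
  bt <- bin_or_table(comb$bins, comb$status, "12 to 13")
  expect_equal(round(bt$or_[bt$bin == "<8"], 2), 0.90)
  expect_equal(round(bt$ci_low[bt$bin == "<8"], 2), 0.46)
  expect_equal(round(bt$ci_high[bt$bin == "<8"], 2), 1.76)
  expect_equal(round(bt$or_[bt$bin == "10 to 11"], 2), 1.20)
  expect_true(is.na(bt$or_[bt$reference]))
  # conservation: bin counts account for every included individual
  expect_equal(sum(bt$cases), sum(comb$status == 1L))
  expect_equal(sum(bt$controls), sum(comb$status == 0L))

  nl <- mk(c(4, 37, 136, 146, 129, 40, 10), c(31, 191, 611, 922, 641, 216, 36))
  bt_nl <- bin_or_table(nl$bins, nl$status, "12 to 13")
  expect_equal(round(bt_nl$or_[bt_nl$bin == "10 to 11"], 2), 1.41)
  expect_equal(round(bt_nl$ci_low[bt_nl$bin == "10 to 11"], 2), 1.09)
  expect_equal(round(bt_nl$ci_high[bt_nl$bin == "10 to 11"], 2), 1.81)
})

test_that("proportional bins give OR 1 and zero cells trigger the 0.5 correction", {
  lev <- levels(bin_scores(0))
  bins <- factor(c(rep("8 to 9", 30), rep("12 to 13", 300),
                   rep("<8", 4)), levels = lev, ordered = TRUE)
  status <- c(rep(c(1L, 0L), c(10, 20)), rep(c(1L, 0L), c(100, 200)),
              rep(0L, 4))
  bt <- bin_or_table(bins, status, "12 to 13")
  expect_equal(bt$or_[bt$bin == "8 to 9"], 1, tolerance = 1e-12)
  zero_row <- bt[bt$bin == "<8", ]
  expect_true(zero_row$corrected)       # no cases in that bin
  expect_true(is.finite(zero_row$or_))
  expect_false(any(bt$corrected[bt$bin == "8 to 9"]))
  expect_error(bin_or_table(bins, rep(1L, length(bins)), "12 to 13"),
               "reference bin")
})

test_that("Woolf CIs equal the saturated logistic Wald CIs", {
  set.seed(121)
  for (i in 1:10) {
    tab <- sample(8:120, 4)
    w <- woolf_or(tab[1], tab[2], tab[3], tab[4])
    fit <- additive_logistic(cohort_from_2x2(tab[1], tab[2], tab[3], tab[4]), "snp1")
    expect_equal(w$ci_low, fit$ci_low, tolerance = 1e-6)
    expect_equal(w$ci_high, fit$ci_high, tolerance = 1e-6)
  }
})

test_that("the trend test equals a first-principles tie-corrected rank statistic", {
  lev <- levels(bin_scores(0))
  bins <- factor(lev[c(1, 1, 2, 3, 3, 3)], levels = lev, ordered = TRUE)
  status <- c(1L, 1L, 1L, 0L, 0L, 0L)
  tr <- grs_trend_test(bins, status)
  expect_equal(tr$statistic, kw_oracle(as.integer(bins), status),
               tolerance = 1e-10)
  expect_equal(tr$statistic, 4.5, tolerance = 1e-10)  # frozen from the oracle
  expect_equal(tr$df, 1)
  # identical case and control bin distributions carry no trend
  b2 <- factor(rep(lev[2:4], 4), levels = lev, ordered = TRUE)
  s2 <- rep(c(1L, 0L), each = 6)
  expect_equal(grs_trend_test(b2, s2)$p, 1, tolerance = 1e-12)
  expect_error(grs_trend_test(factor(rep(lev[1], 4), levels = lev), c(1L, 0L, 1L, 0L)),
               "2 occupied")
})

test_that("adding a risk allele never lowers an individual's bin", {
  set.seed(131)
  scores <- runif(200, 0, 23)
  before <- bin_scores(scores)
  after <- bin_scores(scores + 1)
  expect_true(all(as.integer(after) >= as.integer(before)))
})

test_that("grs_analysis runs the full chain with conserved counts", {
  spec <- sim_spec(150, 350, bmi_panel(), missing_rate = 0.05, seed = 141)
  coh <- simulate_cohort(spec, "grs")
  g <- grs_analysis(coh)
  expect_equal(sum(g$bin_table$cases), unname(g$included["cases"]))
  expect_equal(sum(g$bin_table$controls), unname(g$included["controls"]))
  expect_equal(sum(g$profiles$included) + unname(g$included["excluded"]), 500)
  expect_true(g$reference %in% g$bin_table$bin)
  expect_true(all(g$profiles$score[g$profiles$included] <= 24))
  expect_gt(g$trend$p, 0); expect_lte(g$trend$p, 1)
})
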