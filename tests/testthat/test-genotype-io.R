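test_that("the packaged panel has 12 unique loci with valid frequencies", {
  pan <- bmi_panel()
  expect_equal(nrow(pan), 12)
  expect_false(anyDuplicated(pan$rsid) > 0)
  expect_true(all(pan$overall_risk_freq > 0.2 & pan$overall_risk_freq < 0.84))
  expect_true("rs9939609" %in% pan$rsid[strand_ambiguous(pan)])
})

test_that("ped genotypes become risk-allele dosages regardless of column order", {
  pan <- toy_panel()
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  # map lists SNPs in the opposite order from the panel
  writeLines(c("18\trs17782313\t0\t56002077", "16\trs9939609\t0\t52378028"), map)
  writeLines(c("f1 i1 0 0 0 2 C C A A",    # case: dosage (rs9939609=2, rs17782313=2)
               "f2 i2 0 0 0 1 C T A T",    # control: (1, 1)
               "f3 i3 0 0 0 1 0 0 T T"),   # control: (0, missing)
             ped)
  coh <- suppressWarnings(read_ped_map(ped, map, pan))
  expect_equal(unname(coh$dosages[, "rs9939609"]), c(2, 1, 0))
  expect_equal(unname(coh$dosages[, "rs17782313"]), c(2, 1, NA))
  expect_equal(coh$status, c(1L, 0L, 0L))
  expect_warning(read_ped_map(ped, map, pan), "strand-ambiguous")
})

test_that("unknown ped alleles raise an error naming the SNP", {
  pan <- toy_panel()
  ped <- withr::local_tempfile(fileext = ".ped")
  map <- withr::local_tempfile(fileext = ".map")
  writeLines(c("16\trs9939609\t0\t52378028", "18\trs17782313\t0\t56002077"), map)
  writeLines("f1 i1 0 0 0 1 A A G C", ped)
  expect_error(suppressWarnings(read_ped_map(ped, map, pan)), "rs17782313")
})

test_that("ped/map round-trip preserves hard-call dosages exactly", {
  pan <- bmi_panel()
  spec <- sim_spec(40, 60, pan, missing_rate = 0.1, seed = 17)
  coh <- simulate_cohort(spec, "rt")
  prefix <- file.path(withr::local_tempdir(), "rt")
  write_ped_map(coh, pan, prefix)
  back <- suppressWarnings(read_ped_map(paste0(prefix, ".ped"),
                                        paste0(prefix, ".map"), pan, "rt"))
  expect_equal(back$dosages, coh$dosages, ignore_attr = TRUE)
  expect_equal(back$status, coh$status)
})

test_that("fractional dosages pass through TSV but are rejected as ped", {
  pan <- toy_panel()
  dir <- withr::local_tempdir()
  dos <- file.path(dir, "d.tsv"); phe <- file.path(dir, "p.tsv")
  writeLines(c("id\trs9939609\trs17782313",
               "s1\t1.37\t2", "s2\tNA\t0"), dos)
  writeLines(c("id\tstatus\tbmi", "s1\t2\t29.5", "s2\t1\t24.1"), phe)
  coh <- read_dosage_tsv(dos, pan, phe)
  expect_equal(coh$dosages["s1", "rs9939609"], 1.37)
  expect_true(is.na(coh$dosages["s2", "rs9939609"]))
  expect_equal(coh$status, c(1L, 0L))
  expect_equal(coh$bmi, c(29.5, 24.1))
  expect_error(write_ped_map(coh, pan, file.path(dir, "x")), "fractional")
  # TSV round-trip
  out <- file.path(dir, "d2.tsv")
  write_dosage_tsv(coh, out)
  coh2 <- read_dosage_tsv(out, pan, phe)
  expect_equal(coh2$dosages, coh$dosages)
})

test_that("recoding risk/other alleles flips dosage and inverts the odds ratio", {
  pan <- single_snp_panel(0.35)
  spec <- sim_spec(150, 250, pan, per_allele_or = c(snp1 = 1.4),
                   missing_rate = 0, seed = 23)
  coh <- simulate_cohort(spec, "pol")
  flipped <- coh
  flipped$dosages <- 2 - flipped$dosages
  a <- additive_logistic(coh, "snp1")
  b <- additive_logistic(flipped, "snp1")
  expect_equal(b$beta, -a$beta, tolerance = 1e-8)
  expect_equal(b$or_, 1 / a$or_, tolerance = 1e-8)
})

test_that("HWE exact test matches full enumeration on counts up to 200", {
  cases <- list(c(25, 50, 25), c(57, 14, 50), c(0, 100, 0), c(68, 28, 4),
                c(10, 1, 10), c(3, 100, 5), c(80, 15, 105), c(1, 0, 1))
  for (cnt in cases) {
    expect_equal(hwe_exact_test(cnt[1], cnt[2], cnt[3]),
                 hwe_oracle(cnt[1], cnt[2], cnt[3]),
                 tolerance = 1e-10,
                 label = paste("counts", paste(cnt, collapse = "/")))
  }
  # monomorphic: the observed configuration is the only attainable one
  expect_equal(hwe_exact_test(40, 0, 0), 1.0)
  expect_equal(hwe_exact_test(0, 0, 17), 1.0)
  # mid-frequency equilibrium table: the observed het count is modal, p = 1
  expect_equal(hwe_exact_test(25, 50, 25), 1.0, tolerance = 1e-10)
  # extreme heterozygote excess is vanishingly improbable
  expect_lt(hwe_exact_test(0, 100, 0), 0.001)
  expect_error(hwe_exact_test(0, 0, 0), "zero")
  expect_error(hwe_exact_test(-1, 2, 3), "non-negative")
})

test_that("call rates and flags follow the 95% threshold", {
  d <- matrix(1, nrow = 20, ncol = 2, dimnames = list(NULL, c("s1", "s2")))
  d[1, 2] <- NA
  coh <- new_cohort(as.character(1:20), d, rep(c(0L, 1L), 10), label = "cr")
  cr <- call_rate(coh)
  expect_equal(unname(cr$per_snp), c(1, 0.95))
  expect_equal(length(cr$flagged_snps), 0)
  d[2, 2] <- NA  # rate 0.90 now
  coh2 <- new_cohort(as.character(1:20), d, rep(c(0L, 1L), 10), label = "cr")
  expect_equal(call_rate(coh2)$flagged_snps, "s2")
  expect_true(all(call_rate(coh2)$per_individual %in% c(0.5, 1)))
})

test_that("fractional dosages are rounded for HWE QC with a warning", {
  d <- matrix(c(1.37, 1, 0, 2), 4, 1, dimnames = list(NULL, "s1"))
  coh <- new_cohort(as.character(1:4), d, c(1L, 0L, 1L, 0L), label = "fr")
  expect_warning(cr <- call_rate(coh), "rounded")
  expect_equal(cr$hwe$n_het, 2)  # 1.37 rounds to 1
})
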