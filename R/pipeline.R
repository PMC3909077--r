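#' Run the full analysis pipeline from one configuration
#'
#' Orchestrates simulate/load -> QC -> per-cohort association (overall and
#' BMI-stratified) -> meta-analysis -> genetic risk score -> power, writing
#' plain TSV artifacts per stage so any stage can be re-run standalone, plus
#' a structured exclusion log. All randomness derives from the config seed,
#' so a config run twice produces byte-identical outputs.
#'
#' The YAML config holds: `seed`; `output_dir`; `panel` (`"default"` or a
#' panel TSV path); `cohorts`, a named map where each entry either gives
#' simulation sizes (`n_cases`, `n_controls`, optional `per_allele_or`,
#' `missing_rate`, `baseline_case_odds`) or file input (`dosage` +
#' `phenotype` TSV paths, or `ped` + `map`); optional `meta:
#' {i2_threshold, from_or_table}` where `from_or_table` points to a TSV of
#' published per-cohort OR/CI rows; `grs: {min_completeness}`;
#' `bmi_threshold`; `power`, a list of specs (`freq`, `or`, `alpha`,
#' `n_cases`, `n_controls`); `figure: true` for a score-distribution /
#' odds-ratio figure.
#'
#' @param config path to a YAML config, or an equivalent list.
#' @param output_dir overrides the config's output directory.
#' @return (invisibly) a list of the stage results and output paths.
#' @export
run_pipeline <- function(config, output_dir = NULL) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  out <- output_dir %||% config$output_dir %||% "pipeline_out"
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  panel <- if (is.null(config$panel) || identical(config$panel, "default"))
    bmi_panel() else read_panel(config$panel)
  i2_thr <- config$meta$i2_threshold %||% 0.25
  min_comp <- config$grs$min_completeness %||% 0.9
  bmi_thr <- config$bmi_threshold %||% 30

  wtsv <- function(df, name) {
    p <- file.path(out, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
    p
  }
  excl <- data.frame(stage = character(), cohort = character(),
                     unit = character(), id = character(), reason = character(),
                     stringsAsFactors = FALSE)
  note_excl <- function(stage, cohort, unit, ids, reason) {
    if (!length(ids)) return(invisible())
    excl <<- rbind(excl, data.frame(stage = stage, cohort = cohort, unit = unit,
                                    id = as.character(ids), reason = reason,
                                    stringsAsFactors = FALSE))
  }

  # ---- stage 1: cohorts (simulated or loaded) -----------------------------
  cohorts <- list()
  for (i in seq_along(config$cohorts)) {
    lab <- names(config$cohorts)[i]
    cc <- config$cohorts[[i]]
    if (!is.null(cc$n_cases)) {
      oreff <- cc$per_allele_or %||% 1
      spec <- sim_spec(cc$n_cases, cc$n_controls, panel,
                       per_allele_or = unlist(oreff),
                       baseline_case_odds = cc$baseline_case_odds %||% 0.15,
                       missing_rate = cc$missing_rate %||% 0.05,
                       seed = seed + i)
      coh <- simulate_cohort(spec, label = lab)
    } else if (!is.null(cc$dosage)) {
      coh <- read_dosage_tsv(cc$dosage, panel, cc$phenotype, label = lab)
    } else if (!is.null(cc$ped)) {
      coh <- read_ped_map(cc$ped, cc$map, panel, label = lab)
    } else .stopf("cohort '%s': give simulation sizes, dosage+phenotype, or ped+map", lab)
    cohorts[[lab]] <- coh
    wtsv(data.frame(id = coh$ids, status = coh$status,
                    bmi = coh$bmi %||% NA_real_), sprintf("phenotype_%s.tsv", lab))
    write_dosage_tsv(coh, file.path(out, sprintf("dosage_%s.tsv", lab)))
  }

  # ---- stage 2: QC --------------------------------------------------------
  qc <- list()
  for (lab in names(cohorts)) {
    q <- call_rate(cohorts[[lab]])
    qc[[lab]] <- q
    wtsv(cbind(q$hwe, call_rate = as.numeric(q$per_snp[q$hwe$rsid]),
               flagged = q$hwe$rsid %in% q$flagged_snps),
         sprintf("qc_%s.tsv", lab))
    note_excl("qc", lab, "snp", q$flagged_snps, "LOW_CALL_RATE")
  }

  # ---- stage 3: association (overall + BMI strata) ------------------------
  assoc <- list(); assoc_tabs <- list()
  for (lab in names(cohorts)) {
    coh <- cohorts[[lab]]
    a <- assoc_scan(coh, panel)
    assoc[[lab]] <- a
    wtsv(a, sprintf("association_%s.tsv", lab))
    assoc_tabs[[lab]] <- a
    if (!is.null(coh$bmi)) {
      note_excl("bmi_stratify", lab, "individual",
                coh$ids[is.na(coh$bmi)], "MISSING_BMI")
      st <- suppressMessages(bmi_stratify(coh, bmi_thr))
      wtsv(assoc_scan(st$below, panel), sprintf("association_%s_bmi_lt%g.tsv", lab, bmi_thr))
      wtsv(assoc_scan(st$at_or_above, panel), sprintf("association_%s_bmi_ge%g.tsv", lab, bmi_thr))
    }
  }

  # ---- stage 4: BMI-class prevalence table --------------------------------
  prev <- NULL
  if (all(vapply(cohorts, function(x) !is.null(x$bmi), TRUE))) {
    prev <- lapply(names(cohorts), function(lab) {
      bt <- bmi_class_table(cohorts[[lab]])
      data.frame(cohort = lab, class = colnames(bt$counts),
                 pct_cases = bt$percent["case", ],
                 pct_controls = bt$percent["control", ],
                 chisq = bt$test$statistic, df = bt$test$df, p = bt$test$p)
    })
    prev <- do.call(rbind, prev)
    wtsv(prev, "bmi_prevalence.tsv")
  }

  # ---- stage 5: meta-analysis ---------------------------------------------
  meta <- NULL
  if (length(cohorts) >= 2) {
    per_snp <- do.call(rbind, assoc_tabs)
    est <- per_snp[per_snp$estimable, c("rsid", "cohort", "beta", "se")]
    keep <- names(which(table(est$rsid) >= 2))
    meta <- do.call(rbind, lapply(keep, function(s) {
      rows <- est[est$rsid == s, ]
      cbind(data.frame(rsid = s, stringsAsFactors = FALSE),
            select_model(rows$beta, rows$se, i2_thr))
    }))
    meta <- meta[match(intersect(panel$rsid, meta$rsid), meta$rsid), ]
    meta$footnote <- ifelse(meta$model == "random", "*", "")
    wtsv(meta, "meta.tsv")
  }
  meta_tab <- NULL
  if (!is.null(config$meta$from_or_table)) {
    tab <- utils::read.delim(config$meta$from_or_table, comment.char = "#",
                             stringsAsFactors = FALSE)
    meta_tab <- meta_from_or_table(tab, i2_thr)
    meta_tab$footnote <- ifelse(meta_tab$model == "random", "*", "")
    wtsv(meta_tab, "meta_from_table.tsv")
  }

  # ---- stage 6: genetic risk score ----------------------------------------
  grs <- list()
  combined <- NULL
  for (lab in names(cohorts)) {
    g <- grs_analysis(cohorts[[lab]], min_comp)
    grs[[lab]] <- g
    note_excl("grs", lab, "individual",
              g$profiles$id[!g$profiles$included], "LOW_COMPLETENESS")
    wtsv(g$bin_table, sprintf("grs_%s.tsv", lab))
    inc <- g$profiles$included
    combined <- rbind(combined,
                      data.frame(score = g$profiles$score[inc],
                                 status = cohorts[[lab]]$status[inc]))
  }
  if (!is.null(combined) && nrow(combined)) {
    bins <- bin_scores(combined$score)
    ref <- select_reference_bin(combined$score, combined$status)
    grs$combined <- list(reference = ref,
                         bin_table = bin_or_table(bins, combined$status, ref),
                         trend = grs_trend_test(bins, combined$status))
    wtsv(grs$combined$bin_table, "grs_combined.tsv")
    trend <- do.call(rbind, lapply(names(grs), function(lab) {
      tr <- grs[[lab]]$trend
      data.frame(set = lab, statistic = tr$statistic, df = tr$df, p = tr$p)
    }))
    wtsv(trend, "grs_trend.tsv")
    if (isTRUE(config$figure)) {
      grDevices::png(file.path(out, "grs_figure.png"), 900, 600)
      plot_grs(grs$combined$bin_table)
      grDevices::dev.off()
    }
  }

  # ---- stage 7: power ------------------------------------------------------
  power <- NULL
  if (!is.null(config$power)) {
    power <- do.call(rbind, lapply(config$power, function(ps) {
      data.frame(freq = ps$freq, or_ = ps$or, alpha = ps$alpha %||% 0.05,
                 n_cases = ps$n_cases, n_controls = ps$n_controls,
                 power = case_control_power(ps$freq, ps$or, ps$alpha %||% 0.05,
                                            ps$n_cases, ps$n_controls))
    }))
    wtsv(power, "power.tsv")
  }

  wtsv(excl, "exclusions.tsv")
  invisible(list(cohorts = cohorts, qc = qc, association = assoc,
                 bmi_prevalence = prev, meta = meta, meta_from_table = meta_tab,
                 grs = grs, power = power, exclusions = excl, output_dir = out))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Score-distribution and odds-ratio figure
#'
#' Histogram of the percentage of individuals per score bin with the per-bin
#' odds ratios and confidence intervals overlaid on a secondary axis
#' (log scale), reference bin marked at OR 1.
#'
#' @param bin_table output of [bin_or_table()].
#' @export
plot_grs <- function(bin_table) {
  bt <- bin_table
  pct <- (bt$pct_cases + bt$pct_controls) / 2
  op <- graphics::par(mar = c(5, 4, 2, 4)); on.exit(graphics::par(op))
  bp <- graphics::barplot(pct, names.arg = bt$bin, col = "grey85",
                          ylab = "% of individuals", xlab = "BMI risk-allele count",
                          ylim = c(0, max(pct) * 1.3))
  ors <- ifelse(bt$reference, 1, bt$or_)
  lo <- ifelse(bt$reference, 1, bt$ci_low); hi <- ifelse(bt$reference, 1, bt$ci_high)
  rng <- range(c(lo, hi), na.rm = TRUE)
  sc <- function(x) (log(x) - log(rng[1])) / (log(rng[2]) - log(rng[1])) *
    max(pct) * 1.2
  graphics::points(bp, sc(ors), pch = 19)
  nz <- which(hi > lo)  # the reference bin has no interval to draw
  graphics::arrows(bp[nz], sc(lo[nz]), bp[nz], sc(hi[nz]), angle = 90,
                   code = 3, length = 0.04)
  graphics::abline(h = sc(1), lty = 3)
  at <- pretty(rng, 5); at <- at[at > 0 & at >= rng[1] & at <= rng[2]]
  graphics::axis(4, at = sc(at), labels = at)
  graphics::mtext("odds ratio vs reference bin (log scale)", 4, line = 2.5)
  invisible(bp)
}
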