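#' Meta-analysis of per-cohort effects
#'
#' Inverse-variance fixed-effect pooling of per-cohort log odds ratios,
#' Cochran's Q and I-squared, DerSimonian-Laird random effects, and the
#' model-switching rule used for the combined analysis: fixed effect when
#' I-squared is at most 25%, random effects when it exceeds 25% (strictly).
#' Operates on (log-OR, SE) pairs so it can pool fresh association output or
#' OR/CI rows transcribed from published tables.
#'
#' @name meta_analysis
NULL

#' Standard error of a log odds ratio from its 95% CI
#'
#' Inverts the CI convention exp(beta +/- 1.96 se):
#' se = (log ci_high - log ci_low) / (2 x 1.96). The deviation of log OR
#' from the CI midpoint is returned as a rounding diagnostic (published
#' tables round to two decimals).
#'
#' @param or_ odds ratio point estimate.
#' @param ci_low,ci_high 95% confidence bounds.
#' @param z CI multiplier the interval was built with (default 1.96).
#' @return list with `beta`, `se` and `asymmetry` (log-scale midpoint
#'   deviation).
#' @export
se_from_ci <- function(or_, ci_low, ci_high, z = .Z95) {
  if (any(c(or_, ci_low, ci_high) <= 0)) .stopf("odds ratios and bounds must be positive")
  if (ci_low > or_ || or_ > ci_high) .stopf("need ci_low <= or_ <= ci_high")
  se <- (log(ci_high) - log(ci_low)) / (2 * z)
  if (se == 0) .stopf("zero-width confidence interval is degenerate")
  list(beta = log(or_), se = se,
       asymmetry = abs(log(or_) - (log(ci_low) + log(ci_high)) / 2))
}

.meta_result <- function(beta, se, q, i2, tau2, model, k, z = .Z95) {
  data.frame(beta_pooled = beta, se_pooled = se, or_pooled = exp(beta),
             ci_low = exp(beta - z * se), ci_high = exp(beta + z * se),
             p = 2 * stats::pnorm(-abs(beta / se)),
             q_stat = q, i2 = i2, tau2 = tau2, model = model, k = k,
             stringsAsFactors = FALSE)
}

.check_estimates <- function(beta, se) {
  if (length(beta) < 2) .stopf("meta-analysis needs at least 2 estimates")
  if (length(se) != length(beta)) .stopf("beta and se lengths differ")
  if (any(!is.finite(beta)) || any(!is.finite(se)) || any(se <= 0))
    .stopf("estimates must be finite with positive standard errors")
}

#' Fixed-effect inverse-variance meta-analysis
#'
#' Weights w_i = 1/se_i^2; pooled beta = sum(w b)/sum(w),
#' se = 1/sqrt(sum w); Q = sum w (b - pooled)^2 on k-1 df;
#' I^2 = max(0, (Q - (k-1))/Q).
#'
#' @param beta per-cohort log odds ratios.
#' @param se their standard errors.
#' @param z CI multiplier.
#' @return one-row data frame (see [meta_analysis]); `tau2 = 0`,
#'   `model = "fixed"`.
#' @export
fixed_effect <- function(beta, se, z = .Z95) {
  .check_estimates(beta, se)
  w <- 1 / se^2
  bp <- sum(w * beta) / sum(w)
  q <- sum(w * (beta - bp)^2)
  df <- length(beta) - 1
  i2 <- if (q > 0) max(0, (q - df) / q) else 0
  .meta_result(bp, 1 / sqrt(sum(w)), q, i2, 0, "fixed", length(beta), z)
}

#' DerSimonian-Laird random-effects meta-analysis
#'
#' Method-of-moments between-study variance
#' tau^2 = max(0, (Q - (k-1)) / (sum w - sum w^2 / sum w)) with fixed-effect
#' weights w; pooling then uses w*_i = 1/(se_i^2 + tau^2). With Q <= k-1 the
#' truncation gives tau^2 = 0 and the result equals the fixed-effect one.
#'
#' @inheritParams fixed_effect
#' @return one-row data frame with `model = "random"` and the DL `tau2`;
#'   `q_stat` and `i2` are the fixed-effect heterogeneity statistics.
#' @export
dl_random <- function(beta, se, z = .Z95) {
  fe <- fixed_effect(beta, se, z)
  w <- 1 / se^2
  denom <- sum(w) - sum(w^2) / sum(w)
  tau2 <- if (denom > 0) max(0, (fe$q_stat - (length(beta) - 1)) / denom) else 0
  ws <- 1 / (se^2 + tau2)
  bp <- sum(ws * beta) / sum(ws)
  .meta_result(bp, 1 / sqrt(sum(ws)), fe$q_stat, fe$i2, tau2, "random",
               length(beta), z)
}

#' I-squared model-switching meta-analysis
#'
#' Computes fixed-effect Q and I^2 first; if I^2 strictly exceeds the
#' threshold (default 25%) the DerSimonian-Laird random-effects result is
#' returned, otherwise the fixed-effect one. I^2 exactly at the threshold
#' keeps the fixed-effect model.
#'
#' @inheritParams fixed_effect
#' @param i2_threshold proportion (default 0.25).
#' @return one-row data frame; `model` records which estimator was used.
#' @export
select_model <- function(beta, se, i2_threshold = 0.25, z = .Z95) {
  fe <- fixed_effect(beta, se, z)
  if (fe$i2 > i2_threshold) dl_random(beta, se, z) else fe
}

#' Meta-analyse a table of per-cohort OR/CI rows
#'
#' Convenience wrapper for published-table input: rows carry `rsid`,
#' `cohort`, `or`, `ci_low`, `ci_high`; each SNP's rows are converted with
#' [se_from_ci()] and pooled with [select_model()].
#'
#' @param tab data frame of per-cohort rows.
#' @param i2_threshold passed to [select_model()].
#' @return data frame, one row per SNP, with the pooled columns.
#' @export
meta_from_or_table <- function(tab, i2_threshold = 0.25) {
  need <- c("rsid", "or", "ci_low", "ci_high")
  if (!all(need %in% names(tab))) .stopf("need columns: %s", paste(need, collapse = ", "))
  out <- lapply(split(tab, tab$rsid), function(rows) {
    est <- Map(se_from_ci, rows$or, rows$ci_low, rows$ci_high)
    res <- select_model(vapply(est, `[[`, 0, "beta"),
                        vapply(est, `[[`, 0, "se"), i2_threshold)
    cbind(data.frame(rsid = rows$rsid[1], stringsAsFactors = FALSE), res)
  })
  out <- do.call(rbind, out)
  rownames(out) <- NULL
  out[match(unique(tab$rsid), out$rsid), ]
}
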