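#' One-degree-of-freedom Wald chi-square
#'
#' @param beta Log odds ratio.
#' @param se Its standard error; must be positive.
#' @return A list `chi2 = (beta/se)^2` and `p`, the upper tail of the 1-df
#'   chi-square distribution.
#' @export
wald_chi2 <- function(beta, se) {
  if (any(se <= 0)) stop("se must be positive")
  chi2 <- (beta / se)^2
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Two-degree-of-freedom joint chi-square of the sex-specific statistics
#'
#' Sums the female- and male-specific 1-df Wald statistics and refers the sum
#' to a chi-square with two degrees of freedom, testing for an allelic effect
#' in either sex.
#'
#' @param chi2_f,chi2_m Non-negative sex-specific 1-df statistics.
#' @return A list `chi2`, `p`.
#' @export
joint_2df <- function(chi2_f, chi2_m) {
  if (any(chi2_f < 0) || any(chi2_m < 0)) stop("chi-square inputs must be >= 0")
  chi2 <- chi2_f + chi2_m
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 2, lower.tail = FALSE))
}

#' Heterogeneity test of allelic effects between sexes
#'
#' One-degree-of-freedom chi-square for equality of the female and male
#' log odds ratios: `(beta_f - beta_m)^2 / (se_f^2 + se_m^2 - 2*cov)`.
#' The sexes are disjoint samples, so the between-stratum covariance defaults
#' to zero; a covariance term is exposed for correlated-estimate settings.
#'
#' @param beta_f,se_f Female log OR and standard error.
#' @param beta_m,se_m Male log OR and standard error.
#' @param cov_fm Covariance between the two estimates (default 0).
#' @return A list `chi2`, `p` (upper tail, 1 df).
#' @export
het_test <- function(beta_f, se_f, beta_m, se_m, cov_fm = 0) {
  if (any(se_f <= 0) || any(se_m <= 0)) stop("standard errors must be positive")
  v <- se_f^2 + se_m^2 - 2 * cov_fm
  if (any(v <= 0)) stop("non-positive heterogeneity variance")
  chi2 <- (beta_f - beta_m)^2 / v
  list(chi2 = chi2, p = stats::pchisq(chi2, df = 1, lower.tail = FALSE))
}

#' Recover log-OR and standard error from a printed OR and Wald CI
#'
#' Inverts the Wald interval construction so published tables (OR with 95% CI)
#' can be re-analysed without genotype data: `beta = ln(OR)` and
#' `se = (ln(hi) - ln(lo)) / (2 z)` with `z` the two-sided normal quantile.
#'
#' @param or_ Odds ratio; must satisfy `0 < ci_low < or_ < ci_high`.
#' @param ci_low,ci_high Interval bounds.
#' @param level Confidence level of the printed interval (default 0.95).
#' @return A list `beta`, `se`.
#' @export
beta_se_from_or_ci <- function(or_, ci_low, ci_high, level = 0.95) {
  if (any(!(0 < ci_low & ci_low < or_ & or_ < ci_high))) {
    stop("require 0 < ci_low < or_ < ci_high")
  }
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(beta = log(or_), se = (log(ci_high) - log(ci_low)) / (2 * z))
}

#' Sex-differentiated regression estimate test across a panel
#'
#' Combines female- and male-stratum association results for the same
#' (variant, outcome) pairs into per-pair sex-specific 1-df Wald chi-squares,
#' their 2-df joint sum, and the 1-df heterogeneity test. A pair is flagged
#' as a potential sex difference when the sex-specific Wald P is below
#' `alpha_sex` in at least one sex AND the heterogeneity P is below
#' `alpha_het` (both strict).
#'
#' @param results_f,results_m [assoc_scan()] outputs for the `F` and `M`
#'   strata covering identical (rsid, outcome) pairs. Pairs flagged
#'   `separated`/`degenerate` in either sex are skipped with a message.
#' @param alpha_sex,alpha_het Flagging levels (defaults 0.05, 0.05).
#'
#' @return A tibble with one row per usable pair: `rsid, outcome, beta_f,
#'   se_f, beta_m, se_m, chi2_f, chi2_m, chi2_joint, chi2_het, p_f, p_m,
#'   p_joint, p_het, flagged`.
#' @export
sexdiff_scan <- function(results_f, results_m, alpha_sex = 0.05,
                         alpha_het = 0.05) {
  key_f <- paste(results_f$rsid, results_f$outcome)
  key_m <- paste(results_m$rsid, results_m$outcome)
  if (length(key_f) != length(key_m) || !setequal(key_f, key_m)) {
    diff <- c(setdiff(key_f, key_m), setdiff(key_m, key_f))
    stop("mismatched (variant, outcome) pairs between strata: ",
         paste(diff, collapse = "; "))
  }
  results_m <- results_m[match(key_f, key_m), , drop = FALSE]
  usable <- results_f$status_flag == "ok" & results_m$status_flag == "ok"
  n_skip <- sum(!usable)
  if (n_skip > 0) {
    message("sexdiff_scan: skipping ", n_skip,
            " pair(s) with degenerate/separated fits")
  }
  f <- results_f[usable, , drop = FALSE]
  m <- results_m[usable, , drop = FALSE]
  wf <- wald_chi2(f$beta, f$se)
  wm <- wald_chi2(m$beta, m$se)
  jt <- joint_2df(wf$chi2, wm$chi2)
  ht <- het_test(f$beta, f$se, m$beta, m$se)
  tibble::tibble(
    rsid = f$rsid, outcome = f$outcome,
    beta_f = f$beta, se_f = f$se, beta_m = m$beta, se_m = m$se,
    chi2_f = wf$chi2, chi2_m = wm$chi2,
    chi2_joint = jt$chi2, chi2_het = ht$chi2,
    p_f = wf$p, p_m = wm$p, p_joint = jt$p, p_het = ht$p,
    flagged = (wf$p < alpha_sex | wm$p < alpha_sex) & ht$p < alpha_het
  )
}

#' Sex-differentiated reanalysis of a printed OR/CI table
#'
#' Runs the sex-differentiated test directly from published sex-specific
#' odds ratios and 95% confidence intervals (one row per variant), with no
#' genotype data: log-ORs and standard errors are recovered with
#' [beta_se_from_or_ci()] and fed through [wald_chi2()], [joint_2df()] and
#' [het_test()].
#'
#' @param tab Data frame with columns `rsid, or_f, ci_low_f, ci_high_f, or_m,
#'   ci_low_m, ci_high_m` (and optionally `outcome`, carried through).
#' @param level Confidence level of the printed intervals.
#' @inheritParams sexdiff_scan
#' @return The [sexdiff_scan()] result schema.
#' @export
sexdiff_from_or_ci <- function(tab, level = 0.95, alpha_sex = 0.05,
                               alpha_het = 0.05) {
  need <- c("rsid", "or_f", "ci_low_f", "ci_high_f", "or_m", "ci_low_m", "ci_high_m")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  bf <- beta_se_from_or_ci(tab$or_f, tab$ci_low_f, tab$ci_high_f, level)
  bm <- beta_se_from_or_ci(tab$or_m, tab$ci_low_m, tab$ci_high_m, level)
  wf <- wald_chi2(bf$beta, bf$se); wm <- wald_chi2(bm$beta, bm$se)
  jt <- joint_2df(wf$chi2, wm$chi2)
  ht <- het_test(bf$beta, bf$se, bm$beta, bm$se)
  tibble::tibble(
    rsid = tab$rsid,
    outcome = if ("outcome" %in% names(tab)) tab$outcome else "melanoma",
    beta_f = bf$beta, se_f = bf$se, beta_m = bm$beta, se_m = bm$se,
    chi2_f = wf$chi2, chi2_m = wm$chi2,
    chi2_joint = jt$chi2, chi2_het = ht$chi2,
    p_f = wf$p, p_m = wm$p, p_joint = jt$p, p_het = ht$p,
    flagged = (wf$p < alpha_sex | wm$p < alpha_sex) & ht$p < alpha_het
  )
}
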