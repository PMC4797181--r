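Z975 <- stats::qnorm(0.975)  # 1.959964

#' Additive logistic regression of a binary outcome on dosage
#'
#' Maximum-likelihood fit of `logit P(y = 1) = b0 + b1 * dosage` by
#' iteratively reweighted least squares, the slope being the per-minor-allele
#' log odds ratio. The standard error comes from the inverse observed
#' information. Complete cases only; callers filter beforehand.
#'
#' @param dosage Numeric vector with values in `{0, 1, 2}`.
#' @param outcome Binary 0/1 vector of the same length.
#' @return A list `beta`, `se`, `converged`, `status` where `status` is one of
#'   `"ok"`, `"degenerate"` (single outcome class or constant dosage) or
#'   `"separated"` (estimate escaping beyond |beta| = 15, a perfect-separation
#'   signature; no P value should be reported).
#' @export
fit_additive_logistic <- function(dosage, outcome) {
  keep <- !is.na(dosage) & !is.na(outcome)
  dosage <- dosage[keep]; outcome <- outcome[keep]
  n <- length(dosage)
  if (n < 2) return(list(beta = NA_real_, se = NA_real_, converged = FALSE,
                         status = "degenerate", n_used = n))
  if (length(unique(outcome)) < 2 || length(unique(dosage)) < 2) {
    return(list(beta = NA_real_, se = NA_real_, converged = FALSE,
                status = "degenerate", n_used = n))
  }
  fit <- suppressWarnings(
    stats::glm(outcome ~ dosage, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 50))
  )
  beta <- unname(stats::coef(fit)["dosage"])
  se <- sqrt(diag(stats::vcov(fit)))[["dosage"]]
  if (!is.finite(beta) || abs(beta) > 15) {
    return(list(beta = beta, se = se, converged = fit$converged,
                status = "separated", n_used = n))
  }
  list(beta = beta, se = se, converged = fit$converged, status = "ok",
       n_used = n)
}

#' Odds ratio and Wald confidence interval from a log-OR estimate
#'
#' @param beta Log odds ratio.
#' @param se Standard error of `beta`; must be positive.
#' @param level Confidence level (default 0.95).
#' @return A list `or_`, `ci_low`, `ci_high` where the bounds are
#'   `exp(beta -/+ z * se)` with `z` the two-sided normal quantile
#'   (1.959964 at 0.95).
#' @export
or_ci <- function(beta, se, level = 0.95) {
  if (se <= 0) stop("se must be positive")
  z <- stats::qnorm(1 - (1 - level) / 2)
  list(or_ = exp(beta), ci_low = exp(beta - z * se), ci_high = exp(beta + z * se))
}

#' Scan a panel for association with one outcome in one sex stratum
#'
#' Fits [fit_additive_logistic()] for every variant against the named outcome
#' (six traits or melanoma status) within a sex stratum, with per-(variant,
#' outcome) complete-case filtering and no covariate adjustment. Each row is
#' annotated as significant at the trait-reporting level (`alpha_report`,
#' default 0.01 from a Bonferroni split of 0.05 over six traits) and at the
#' enrichment-eligibility level (`alpha_enrich`, default 0.05).
#'
#' @param gm A QC-passed, oriented [genotype_matrix()].
#' @param samples A [sample_records()] table.
#' @param outcome One of `eye, hair, skin, naevi, lentigines, sunburn,
#'   melanoma`.
#' @param stratum `"F"`, `"M"` or `"all"` (combined sexes).
#' @param alpha_report,alpha_enrich Significance annotation levels.
#'
#' @return A tibble with one row per variant:
#'   `rsid, stratum, outcome, n_used, beta, se, or_, ci_low, ci_high, p,
#'   status_flag, sig_report, sig_enrich`. P values are two-sided Wald.
#' @export
assoc_scan <- function(gm, samples, outcome, stratum = c("F", "M", "all"),
                       alpha_report = 0.01, alpha_enrich = 0.05) {
  stratum <- match.arg(stratum)
  outcome <- match.arg(outcome, OUTCOME_NAMES)
  sex <- samples$sex[match(gm$samples, samples$sample_id)]
  idx <- if (stratum == "all") !is.na(sex) else !is.na(sex) & sex == stratum
  if (!any(idx)) stop("empty stratum: ", stratum)
  y_all <- outcome_vector(samples, outcome)[match(gm$samples, samples$sample_id)]
  nv <- nrow(gm$variants)
  res <- vector("list", nv)
  for (j in seq_len(nv)) {
    fit <- fit_additive_logistic(gm$dosage[idx, j], y_all[idx])
    if (fit$status == "ok") {
      ci <- or_ci(fit$beta, fit$se)
      p <- 2 * stats::pnorm(-abs(fit$beta / fit$se))
      res[[j]] <- tibble::tibble(
        rsid = gm$variants$rsid[j], stratum = stratum, outcome = outcome,
        n_used = fit$n_used, beta = fit$beta, se = fit$se, or_ = ci$or_,
        ci_low = ci$ci_low, ci_high = ci$ci_high, p = p,
        status_flag = "ok",
        sig_report = p < alpha_report, sig_enrich = p < alpha_enrich
      )
    } else {
      res[[j]] <- tibble::tibble(
        rsid = gm$variants$rsid[j], stratum = stratum, outcome = outcome,
        n_used = fit$n_used, beta = NA_real_, se = NA_real_, or_ = NA_real_,
        ci_low = NA_real_, ci_high = NA_real_, p = NA_real_,
        status_flag = fit$status, sig_report = FALSE, sig_enrich = FALSE
      )
    }
  }
  dplyr::bind_rows(res)
}
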