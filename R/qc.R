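#' Filter variants by call rate
#'
#' Removes variants whose fraction of non-missing genotype calls falls below
#' `min_call_rate`. This is the dosage-level analogue of instrument-level
#' genotyping-failure triage: assays that fail (no amplification, poor cluster
#' separation) surface as missing calls.
#'
#' @param gm A [genotype_matrix()].
#' @param min_call_rate Minimum non-missing fraction in `[0, 1]` (default 0.9).
#'
#' @return A list with `genotypes` (the filtered matrix), and `report`: a list
#'   with `removed` (rsIDs), `n_removed`, `n_retained`, `removal_fraction` and
#'   per-variant call rates. If every variant is removed the report carries a
#'   warning message and the matrix is empty.
#' @export
call_rate_filter <- function(gm, min_call_rate = 0.9) {
  if (min_call_rate < 0 || min_call_rate > 1) stop("min_call_rate must be in [0, 1]")
  call_rate <- colMeans(!is.na(gm$dosage))
  keep <- call_rate >= min_call_rate
  report <- list(
    removed = gm$variants$rsid[!keep],
    n_removed = sum(!keep), n_retained = sum(keep),
    removal_fraction = mean(!keep),
    call_rate = setNames(call_rate, gm$variants$rsid),
    warning = NULL
  )
  if (!any(keep)) report$warning <- "all variants removed by call-rate filter"
  list(genotypes = subset_variants(gm, keep), report = report)
}

#' Orient dosages to the sample minor allele
#'
#' For each variant, if the pooled-sample frequency of the coded allele
#' exceeds 0.5 the dosages are reflected (`d -> 2 - d`) and the allele labels
#' swapped, so that the coded allele is the minor allele in this sample.
#' A frequency of exactly 0.5 keeps the input orientation. Idempotent.
#'
#' @param gm A [genotype_matrix()].
#' @param samples Optional [sample_records()]; when given, X-chromosome
#'   frequencies count males as hemizygous (one allele). Without it all
#'   samples are treated as diploid.
#' @param x_mode `"hemizygous"` (default) or `"autosomal"` X handling.
#'
#' @return The re-oriented `genotype_matrix`.
#' @export
orient_minor_allele <- function(gm, samples = NULL, x_mode = c("hemizygous", "autosomal")) {
  x_mode <- match.arg(x_mode)
  freq <- coded_allele_freq(gm, samples, x_mode)
  flip <- !is.na(freq) & freq > 0.5
  if (any(flip)) {
    gm$dosage[, flip] <- 2L - gm$dosage[, flip]
    if (!is.null(samples) && x_mode == "hemizygous") {
      male <- gm$samples %in% samples$sample_id[samples$sex == "M"]
      on_x <- gm$variants$chrom == "X"
      fx <- flip & on_x
      if (any(fx) && any(male)) {
        # hemizygous males flip 0 <-> 1, not 0 <-> 2
        gm$dosage[male, fx] <- 1L - (2L - gm$dosage[male, fx, drop = FALSE])
      }
    }
    ma <- gm$variants$minor_allele[flip]
    gm$variants$minor_allele[flip] <- gm$variants$major_allele[flip]
    gm$variants$major_allele[flip] <- ma
  }
  gm
}

# frequency of the currently coded allele, per variant
coded_allele_freq <- function(gm, samples = NULL, x_mode = "hemizygous") {
  d <- gm$dosage
  if (is.null(samples) || x_mode == "autosomal" || !any(gm$variants$chrom == "X")) {
    return(colSums(d, na.rm = TRUE) / (2 * colSums(!is.na(d))))
  }
  male <- gm$samples %in% samples$sample_id[samples$sex == "M"]
  freq <- numeric(ncol(d))
  for (j in seq_len(ncol(d))) {
    dj <- d[, j]
    if (gm$variants$chrom[j] == "X") {
      df <- dj[!male]; dm <- dj[male]
      dm <- pmin(dm, 1L)  # hemizygous: any copy counts once
      cnt <- sum(df, na.rm = TRUE) + sum(dm, na.rm = TRUE)
      tot <- 2 * sum(!is.na(df)) + sum(!is.na(dm))
    } else {
      cnt <- sum(dj, na.rm = TRUE); tot <- 2 * sum(!is.na(dj))
    }
    freq[j] <- if (tot > 0) cnt / tot else NA_real_
  }
  freq
}

#' Exact test for Hardy-Weinberg equilibrium
#'
#' Exact conditional (Fisher-type) test on genotype counts given allele
#' counts: conditioning on the observed number of minor alleles, the P value
#' is the sum of probabilities of all heterozygote counts whose conditional
#' probability does not exceed that of the observed configuration. A
#' monomorphic variant returns 1.
#'
#' @param n_AA,n_Aa,n_aa Non-negative genotype counts, `A` the minor allele.
#' @return Exact P value in `(0, 1]`.
#' @export
hwe_exact_test <- function(n_AA, n_Aa, n_aa) {
  if (any(c(n_AA, n_Aa, n_aa) < 0)) stop("genotype counts must be non-negative")
  n <- n_AA + n_Aa + n_aa
  if (n == 0) stop("at least one genotype required")
  nA <- 2L * n_AA + n_Aa                     # minor allele count
  if (nA == 0L || nA == 2L * n) return(1)    # monomorphic
  # possible heterozygote counts share the parity of nA
  hets <- seq(nA %% 2L, min(nA, 2L * n - nA), by = 2L)
  # log conditional probability of each heterozygote count given margins
  lp <- lgamma(n + 1) - lgamma((nA - hets) / 2 + 1) - lgamma(hets + 1) -
    lgamma(n - (nA + hets) / 2 + 1) + hets * log(2) +
    lgamma(nA + 1) + lgamma(2 * n - nA + 1) - lgamma(2 * n + 1)
  p <- exp(lp - max(lp)); p <- p / sum(p)
  obs <- p[match(n_Aa, hets)]
  min(1, sum(p[p <= obs * (1 + 1e-7)]))
}

# genotype counts of the minor allele within a stratum
genotype_counts <- function(dosage) {
  c(n_AA = sum(dosage == 2L, na.rm = TRUE),
    n_Aa = sum(dosage == 1L, na.rm = TRUE),
    n_aa = sum(dosage == 0L, na.rm = TRUE))
}

#' Screen a panel for Hardy-Weinberg disequilibrium
#'
#' Runs [hwe_exact_test()] per variant in females, males and the pooled
#' sample, and flags variants out of HWE at the Bonferroni-corrected level
#' `alpha / m`. "In HWE" means `p_exact >= threshold` (strict inequality for
#' failure), so a P value exactly at the threshold passes. X-linked variants
#' are tested in females only under hemizygous X handling (a genotype-level
#' HWE test is undefined for hemizygous males); their `M` rows carry `NA`.
#'
#' @param gm An oriented [genotype_matrix()].
#' @param samples A [sample_records()] table covering the matrix samples.
#' @param alpha Family-wise level (default 0.05).
#' @param m Number of tests for Bonferroni (default: number of variants).
#' @param x_mode `"hemizygous"` or `"autosomal"`.
#'
#' @return A list: `results`, a tibble with one row per variant x stratum
#'   (`rsid, stratum, n_AA, n_Aa, n_aa, p_exact, out_of_hwe`), and
#'   `threshold`, the Bonferroni threshold `alpha/m`. The pooled-stratum flag
#'   is the per-variant verdict.
#' @export
hwe_screen <- function(gm, samples, alpha = 0.05, m = nrow(gm$variants),
                       x_mode = c("hemizygous", "autosomal")) {
  x_mode <- match.arg(x_mode)
  if (m < 1) stop("m must be >= 1")
  threshold <- alpha / m
  sex <- samples$sex[match(gm$samples, samples$sample_id)]
  strata <- list(F = sex == "F", M = sex == "M", all = rep(TRUE, length(sex)))
  out <- vector("list", 3L * nrow(gm$variants))
  k <- 0L
  for (j in seq_len(nrow(gm$variants))) {
    on_x <- gm$variants$chrom[j] == "X" && x_mode == "hemizygous"
    for (s in names(strata)) {
      k <- k + 1L
      idx <- strata[[s]]
      if (on_x && s != "F") idx <- idx & sex == "F"  # X: females only
      cnt <- genotype_counts(gm$dosage[idx, j])
      p <- if (on_x && s != "F") NA_real_ else if (sum(cnt) == 0) NA_real_ else
        hwe_exact_test(cnt["n_AA"], cnt["n_Aa"], cnt["n_aa"])
      out[[k]] <- tibble::tibble(
        rsid = gm$variants$rsid[j], stratum = s,
        n_AA = unname(cnt["n_AA"]), n_Aa = unname(cnt["n_Aa"]),
        n_aa = unname(cnt["n_aa"]),
        p_exact = p, out_of_hwe = !is.na(p) & p < threshold
      )
    }
  }
  list(results = dplyr::bind_rows(out), threshold = threshold)
}

#' Minor-allele frequencies by sex
#'
#' Per-variant minor-allele frequencies in females, males and the pooled
#' sample over non-missing genotypes, plus the panel-level squared Pearson
#' correlation between the two sex-specific frequency vectors. X-linked
#' variants count males as one allele under hemizygous handling.
#'
#' @inheritParams hwe_screen
#' @return A list: `summary` tibble (`rsid, maf_f, maf_m, maf_all, n_f, n_m`)
#'   and `r_squared` (scalar, computed over variants with both frequencies
#'   defined).
#' @export
maf_by_sex <- function(gm, samples, x_mode = c("hemizygous", "autosomal")) {
  x_mode <- match.arg(x_mode)
  sex <- samples$sex[match(gm$samples, samples$sample_id)]
  fem <- sex == "F"; mal <- sex == "M"
  nv <- nrow(gm$variants)
  maf_f <- maf_m <- maf_all <- rep(NA_real_, nv)
  n_f <- n_m <- integer(nv)
  for (j in seq_len(nv)) {
    dj <- gm$dosage[, j]
    on_x <- gm$variants$chrom[j] == "X" && x_mode == "hemizygous"
    fr <- function(d, hemi) {
      if (hemi) d <- pmin(d, 1L)
      tot <- (if (hemi) 1 else 2) * sum(!is.na(d))
      if (tot == 0) NA_real_ else sum(d, na.rm = TRUE) / tot
    }
    maf_f[j] <- fr(dj[fem], FALSE)
    maf_m[j] <- fr(dj[mal], on_x)
    n_f[j] <- sum(!is.na(dj[fem])); n_m[j] <- sum(!is.na(dj[mal]))
    # pooled allele frequency respecting hemizygosity
    cf <- sum(dj[fem], na.rm = TRUE)
    cm <- sum(if (on_x) pmin(dj[mal], 1L) else dj[mal], na.rm = TRUE)
    tot <- 2 * n_f[j] + (if (on_x) 1 else 2) * n_m[j]
    maf_all[j] <- if (tot > 0) (cf + cm) / tot else NA_real_
  }
  ok <- !is.na(maf_f) & !is.na(maf_m)
  r2 <- if (sum(ok) >= 2) stats::cor(maf_f[ok], maf_m[ok])^2 else NA_real_
  list(
    summary = tibble::tibble(rsid = gm$variants$rsid, maf_f = maf_f,
                             maf_m = maf_m, maf_all = maf_all,
                             n_f = n_f, n_m = n_m),
    r_squared = r2
  )
}

#' Compare allele counts between sexes
#'
#' Two-sided Fisher exact test on the 2x2 table of minor/major allele counts
#' by sex for one variant. Under hemizygous X handling, females contribute two
#' alleles per genotype and males one.
#'
#' @inheritParams hwe_screen
#' @param rsid Variant identifier.
#' @return Two-sided exact P value.
#' @export
allele_count_sex_test <- function(gm, samples, rsid,
                                  x_mode = c("hemizygous", "autosomal")) {
  x_mode <- match.arg(x_mode)
  j <- match(rsid, gm$variants$rsid)
  if (is.na(j)) stop("variant not in panel: ", rsid)
  sex <- samples$sex[match(gm$samples, samples$sample_id)]
  on_x <- gm$variants$chrom[j] == "X" && x_mode == "hemizygous"
  counts <- function(d, hemi) {
    if (hemi) d <- pmin(d, 1L)
    tot <- (if (hemi) 1 else 2) * sum(!is.na(d))
    c(minor = sum(d, na.rm = TRUE), major = tot - sum(d, na.rm = TRUE))
  }
  cf <- counts(gm$dosage[sex == "F", j], FALSE)
  cm <- counts(gm$dosage[sex == "M", j], on_x)
  if (sum(cf) == 0 || sum(cm) == 0) {
    stop("no alleles observed in one sex stratum for ", rsid)
  }
  stats::fisher.test(cbind(F = cf, M = cm))$p.value
}
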