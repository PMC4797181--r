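#' Simulation configuration for a synthetic sex-stratified study
#'
#' Defines a genotype-phenotype dataset with the structure the analysis
#' assumes: a case-control sample stratified by sex, a panel of independent
#' SNPs in Hardy-Weinberg proportions with MAF in `[0.05, 0.5]`, six binary
#' traits and melanoma status generated from additive logistic models with
#' sex-specific per-allele log odds ratios. Defaults reproduce the study
#' layout: 316/283 female cases/controls, 234/224 male, 363 SNPs.
#'
#' @param n_female_case,n_female_control,n_male_case,n_male_control Sample
#'   counts (defaults 316, 283, 234, 224).
#' @param n_snps Panel size (default 363).
#' @param n_x_snps How many panel SNPs (the last ones) sit on chromosome X
#'   with hemizygous males (default 6, mirroring an X-linked candidate-gene
#'   region in the panel).
#' @param maf_law Function `(n) -> MAF vector` in `[0.05, 0.5]`; default
#'   uniform on that interval.
#' @param effects Tibble/data.frame of true effects with columns
#'   `snp` (panel index), `outcome` (one of the six traits or `melanoma`),
#'   `beta_f`, `beta_m` (per-allele log ORs). `NULL` for a null panel.
#' @param trait_prevalence Baseline (dosage 0) probability of the risk
#'   phenotype for each trait (default 0.5).
#' @param disease_beta0 Baseline log-odds of melanoma in the liability model
#'   (default 0).
#' @param missing_rate Fraction of genotype calls set missing (default 0.01).
#' @param seed Integer seed; identical config + seed gives identical output.
#'
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_female_case = 316, n_female_control = 283,
                       n_male_case = 234, n_male_control = 224,
                       n_snps = 363, n_x_snps = 6,
                       maf_law = function(n) runif(n, 0.05, 0.5),
                       effects = NULL, trait_prevalence = 0.5,
                       disease_beta0 = 0, missing_rate = 0.01, seed = 1L) {
  counts <- c(n_female_case, n_female_control, n_male_case, n_male_control)
  if (any(counts <= 0)) stop("all sample counts must be positive")
  if (missing_rate < 0 || missing_rate >= 1) stop("missing_rate must be in [0, 1)")
  if (n_x_snps < 0 || n_x_snps > n_snps) stop("n_x_snps must be in [0, n_snps]")
  if (!is.null(effects)) {
    effects <- tibble::as_tibble(effects)
    need <- c("snp", "outcome", "beta_f", "beta_m")
    miss <- setdiff(need, names(effects))
    if (length(miss)) stop("effects missing column(s): ", paste(miss, collapse = ", "))
    if (any(effects$snp < 1 | effects$snp > n_snps)) stop("effect snp index out of range")
    if (!all(effects$outcome %in% OUTCOME_NAMES)) stop("unknown effect outcome")
  }
  structure(list(
    n_female_case = n_female_case, n_female_control = n_female_control,
    n_male_case = n_male_case, n_male_control = n_male_control,
    n_snps = n_snps, n_x_snps = n_x_snps, maf_law = maf_law,
    effects = effects, trait_prevalence = trait_prevalence,
    disease_beta0 = disease_beta0, missing_rate = missing_rate,
    seed = as.integer(seed)
  ), class = "sim_config")
}

#' Draw genotype dosages under Hardy-Weinberg proportions
#'
#' Each diploid dosage is the sum of two independent Bernoulli(maf) allele
#' draws; hemizygous (X-chromosome male) dosages are a single draw in
#' `{0, 1}`.
#'
#' @param maf Minor-allele frequency in `(0, 0.5]`.
#' @param n Number of samples.
#' @param hemizygous Draw one allele instead of two (default `FALSE`).
#' @param seed Optional integer seed applied before drawing.
#' @return Integer dosage vector.
#' @export
sample_genotypes <- function(maf, n, hemizygous = FALSE, seed = NULL) {
  if (maf <= 0 || maf > 0.5) stop("maf must be in (0, 0.5]")
  if (!is.null(seed)) set.seed(seed)
  rbinom(n, size = if (hemizygous) 1L else 2L, prob = maf)
}

#' Simulate a binary outcome from an additive logistic model
#'
#' Draws `y ~ Bernoulli(plogis(beta0 + beta * dosage))` per sample.
#'
#' @param dosages Dosage vector.
#' @param beta0 Intercept (baseline log-odds).
#' @param beta Per-allele log odds ratio.
#' @param seed Optional integer seed applied before drawing.
#' @return Integer 0/1 vector.
#' @export
simulate_binary_outcome <- function(dosages, beta0, beta, seed = NULL) {
  if (!is.finite(beta0)) stop("beta0 must be finite")
  if (!is.null(seed)) set.seed(seed)
  rbinom(length(dosages), 1L, plogis(beta0 + beta * dosages))
}

# one sex stratum: rejection-sample individuals (genotypes + disease draw)
# until the case and control buckets hold exactly the configured counts.
sample_stratum <- function(cfg, maf, on_x, sex) {
  n_case <- if (sex == "F") cfg$n_female_case else cfg$n_male_case
  n_ctrl <- if (sex == "F") cfg$n_female_control else cfg$n_male_control
  eff <- cfg$effects
  mel <- if (!is.null(eff)) eff[eff$outcome == "melanoma", , drop = FALSE] else NULL
  bcol <- if (sex == "F") "beta_f" else "beta_m"
  hemi <- on_x & (sex == "M")
  n_target <- n_case + n_ctrl
  case_rows <- ctrl_rows <- list()
  n_cases <- n_ctrls <- 0L
  draws <- 0L; max_draws <- 1e6
  batch <- max(256L, 2L * n_target)
  while (n_cases < n_case || n_ctrls < n_ctrl) {
    if (draws >= max_draws) {
      stop("rejection sampling exceeded ", max_draws,
           " draws; reduce melanoma effect sizes or intercept")
    }
    batch <- min(batch, max_draws - draws)
    g <- matrix(0L, batch, cfg$n_snps)
    for (j in seq_len(cfg$n_snps)) {
      g[, j] <- rbinom(batch, size = if (hemi[j]) 1L else 2L, prob = maf[j])
    }
    eta <- rep(cfg$disease_beta0, batch)
    if (!is.null(mel) && nrow(mel) > 0) {
      for (i in seq_len(nrow(mel))) {
        eta <- eta + mel[[bcol]][i] * g[, mel$snp[i]]
      }
    }
    y <- rbinom(batch, 1L, plogis(eta))
    draws <- draws + batch
    need_case <- n_case - n_cases
    take_case <- which(y == 1L)[seq_len(min(need_case, sum(y == 1L)))]
    if (length(take_case)) {
      case_rows[[length(case_rows) + 1L]] <- g[take_case, , drop = FALSE]
      n_cases <- n_cases + length(take_case)
    }
    need_ctrl <- n_ctrl - n_ctrls
    take_ctrl <- which(y == 0L)[seq_len(min(need_ctrl, sum(y == 0L)))]
    if (length(take_ctrl)) {
      ctrl_rows[[length(ctrl_rows) + 1L]] <- g[take_ctrl, , drop = FALSE]
      n_ctrls <- n_ctrls + length(take_ctrl)
    }
  }
  list(case = do.call(rbind, case_rows), control = do.call(rbind, ctrl_rows))
}

#' Generate a full synthetic study
#'
#' Builds a complete dataset under a [sim_config()]: per-sex genotypes at the
#' configured MAFs (Hardy-Weinberg, independent SNPs; hemizygous males on X),
#' melanoma case-control status realised by rejection sampling against the
#' configured logistic liability so the case/control counts are hit exactly,
#' six trait columns simulated from their own logistic models given genotype
#' (independently of melanoma status), and genotype missingness applied
#' uniformly at random.
#'
#' @param config A [sim_config()].
#' @return A list: `genotypes` ([genotype_matrix()]), `samples`
#'   ([sample_records()]), `truth` (tibble of every nonzero true effect:
#'   `snp, rsid, outcome, beta_f, beta_m`), and `maf` (the true MAF vector).
#' @export
generate_study <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  cfg <- config
  set.seed(cfg$seed)
  maf <- cfg$maf_law(cfg$n_snps)
  if (any(maf < 0.05 - 1e-12 | maf > 0.5 + 1e-12)) {
    stop("maf_law produced frequencies outside [0.05, 0.5]")
  }
  chrom <- rep(as.character(1:22), length.out = cfg$n_snps)
  if (cfg$n_x_snps > 0) {
    chrom[(cfg$n_snps - cfg$n_x_snps + 1L):cfg$n_snps] <- "X"
  }
  on_x <- chrom == "X"
  variants <- variant_info(
    rsid = sprintf("rs%07d", seq_len(cfg$n_snps)), chrom = chrom,
    pos = 10000L + 1000L * seq_len(cfg$n_snps),
    gene = sprintf("GENE%03d", ((seq_len(cfg$n_snps) - 1L) %/% 6L) + 1L),
    minor_allele = "A", major_allele = "G"
  )

  fem <- sample_stratum(cfg, maf, on_x, "F")
  mal <- sample_stratum(cfg, maf, on_x, "M")
  dosage <- rbind(fem$case, fem$control, mal$case, mal$control)
  n_tot <- nrow(dosage)
  sample_id <- sprintf("S%04d", seq_len(n_tot))
  sex <- c(rep("F", cfg$n_female_case + cfg$n_female_control),
           rep("M", cfg$n_male_case + cfg$n_male_control))
  status <- c(rep("case", cfg$n_female_case), rep("control", cfg$n_female_control),
              rep("case", cfg$n_male_case), rep("control", cfg$n_male_control))

  # traits: logistic in dosage, independent of status given genotype
  beta0_trait <- stats::qlogis(cfg$trait_prevalence)
  traits <- matrix(NA_integer_, n_tot, length(TRAIT_NAMES),
                   dimnames = list(NULL, TRAIT_NAMES))
  eff <- cfg$effects
  for (t in TRAIT_NAMES) {
    eta <- rep(beta0_trait, n_tot)
    if (!is.null(eff)) {
      et <- eff[eff$outcome == t, , drop = FALSE]
      for (i in seq_len(nrow(et))) {
        b <- ifelse(sex == "F", et$beta_f[i], et$beta_m[i])
        eta <- eta + b * dosage[, et$snp[i]]
      }
    }
    traits[, t] <- rbinom(n_tot, 1L, plogis(eta))
  }

  if (cfg$missing_rate > 0) {
    drop <- matrix(runif(length(dosage)) < cfg$missing_rate, n_tot)
    dosage[drop] <- NA_integer_
  }

  samples <- sample_records(sample_id, sex, status,
                            eye = traits[, "eye"], hair = traits[, "hair"],
                            skin = traits[, "skin"], naevi = traits[, "naevi"],
                            lentigines = traits[, "lentigines"],
                            sunburn = traits[, "sunburn"])
  truth <- if (is.null(eff) || nrow(eff) == 0) {
    tibble::tibble(snp = integer(), rsid = character(), outcome = character(),
                   beta_f = numeric(), beta_m = numeric())
  } else {
    tibble::tibble(snp = eff$snp, rsid = variants$rsid[eff$snp],
                   outcome = eff$outcome, beta_f = eff$beta_f,
                   beta_m = eff$beta_m)
  }
  list(genotypes = genotype_matrix(dosage, variants, samples = sample_id),
       samples = samples, truth = truth, maf = maf)
}
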