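panel_of <- function(dos, chrom = "1") {
  dos <- as.matrix(dos)
  rownames(dos) <- sprintf("s%03d", seq_len(nrow(dos)))
  genotype_matrix(dos, variant_info(
    sprintf("rs%d", seq_len(ncol(dos))),
    chrom = rep(chrom, length.out = ncol(dos)),
    pos = seq_len(ncol(dos)), gene = ".", minor_allele = "A",
    major_allele = "G"
  ))
}

test_that("call-rate filter removes low-call variants and reports them", {
  dos <- cbind(c(0L, 1L, 2L, 0L), c(NA, NA, NA, NA), c(0L, NA, 1L, 1L))
  gm <- panel_of(dos)
  out <- call_rate_filter(gm, 0.9)
  expect_equal(out$genotypes$variants$rsid, "rs1")
  expect_setequal(out$report$removed, c("rs2", "rs3"))
  expect_equal(out$report$removal_fraction, 2 / 3)

  # threshold 0 is the identity
  ident <- call_rate_filter(gm, 0)
  expect_equal(nrow(ident$genotypes$variants), 3L)

  # panel-scale accounting: 384 variants, 21 fully missing -> 363 retained
  set.seed(3)
  big <- matrix(rbinom(20 * 384, 2, 0.3), nrow = 20)
  big[, 1:21] <- NA
  res <- call_rate_filter(panel_of(big), 0.9)
  expect_equal(res$report$n_retained, 363L)
  expect_equal(res$report$n_removed, 21L)

  allgone <- call_rate_filter(panel_of(matrix(NA_integer_, 3, 2)), 0.5)
  expect_match(allgone$report$warning, "all variants removed")
  expect_equal(ncol(allgone$genotypes$dosage), 0L)
})

test_that("minor-allele orientation reflects majority-coded variants and is idempotent", {
  gm <- panel_of(cbind(c(2L, 2L, 1L), c(0L, 0L, 1L), c(0L, 1L, NA)))
  out <- orient_minor_allele(gm)
  expect_equal(unname(out$dosage[, 1]), c(0L, 0L, 1L))       # freq 5/6 flipped
  expect_equal(out$variants$minor_allele[1], "G")
  expect_equal(unname(out$dosage[, 2]), c(0L, 0L, 1L))       # already minor
  expect_equal(out$variants$minor_allele[2], "A")
  expect_identical(orient_minor_allele(out)$dosage, out$dosage)

  # frequency exactly 0.5 keeps the input orientation
  tie <- panel_of(matrix(c(2L, 0L, 1L, 1L), ncol = 1))
  expect_identical(orient_minor_allele(tie)$dosage, tie$dosage)
})

test_that("exact HWE test matches its stated examples and enumeration oracle", {
  expect_equal(hwe_exact_test(25, 50, 25), 1)
  expect_equal(hwe_exact_test(1, 0, 1), 1 / 3)
  expect_equal(hwe_exact_test(0, 0, 50), 1)
  expect_error(hwe_exact_test(-1, 0, 1), "non-negative")

  # spot equivalence with the factorial enumeration oracle (full sweep in the
  # acceptance suite)
  set.seed(42)
  for (i in 1:200) {
    n <- sample(2:50, 1)
    aa <- sample(0:n, 1); ab <- sample(0:(n - aa), 1)
    expect_equal(hwe_exact_test(aa, ab, n - aa - ab),
                 hwe_oracle(aa, ab, n - aa - ab), tolerance = 1e-12)
  }
})

test_that("Bonferroni HWE screening flags only sub-threshold variants", {
  # deliberately out-of-HWE variant (excess homozygotes) next to a clean one
  dos <- cbind(rep(c(0L, 2L), each = 25),
               rbinom(50, 2, 0.4))
  samples <- sample_records(sprintf("s%03d", 1:50),
                            rep(c("F", "M"), 25), rep("control", 50))
  scr <- hwe_screen(panel_of(dos), samples, alpha = 0.05, m = 363)
  expect_equal(scr$threshold, 0.05 / 363)
  pooled <- scr$results[scr$results$stratum == "all", ]
  expect_true(pooled$out_of_hwe[pooled$rsid == "rs1"])
  expect_false(pooled$out_of_hwe[pooled$rsid == "rs2"])
  # genotype counts partition the non-missing calls
  expect_equal(pooled$n_AA + pooled$n_Aa + pooled$n_aa, c(50L, 50L))

  # a P value exactly at the threshold passes (strict inequality)
  expect_false(0.05 / 363 < 0.05 / 363)
})

test_that("HWE flagging under true equilibrium is Bonferroni-conservative", {
  set.seed(19)
  m <- 1000
  flagged <- 0L
  thr <- 0.05 / m
  for (i in seq_len(m)) {
    d <- rbinom(120, 2, runif(1, 0.05, 0.5))
    cnt <- c(sum(d == 2), sum(d == 1), sum(d == 0))
    if (hwe_exact_test(cnt[1], cnt[2], cnt[3]) < thr) flagged <- flagged + 1L
  }
  expect_lte(flagged / m, 0.05)
})

test_that("per-sex MAF summaries and their correlation behave as expected", {
  set.seed(5)
  # identical dosage distribution in both sexes -> identical frequencies
  d <- rbinom(40, 2, 0.3)
  gm <- panel_of(matrix(c(d, d), ncol = 1))
  samples <- sample_records(sprintf("s%03d", 1:80),
                            rep(c("F", "M"), each = 40), "control")
  mb <- maf_by_sex(gm, samples)
  expect_equal(mb$summary$maf_f, mb$summary$maf_m)

  # simulated panel, both sexes from the same MAFs, study-scale n
  mafs <- runif(200, 0.05, 0.5)
  df <- sapply(mafs, function(p) rbinom(500, 2, p))
  dm <- sapply(mafs, function(p) rbinom(450, 2, p))
  gm2 <- panel_of(rbind(df, dm))
  s2 <- sample_records(sprintf("s%03d", 1:950),
                       rep(c("F", "M"), c(500, 450)), "control")
  mb2 <- maf_by_sex(gm2, s2)
  expect_gte(mb2$r_squared, 0.95)
  expect_true(all(mb2$summary$maf_all <= 0.5 + 0.05))  # oriented upstream in use
})

test_that("between-sex allele-count test matches exact enumeration", {
  # identical allele counts -> P = 1
  d <- c(rep(0L, 10), rep(1L, 6), rep(2L, 4))
  gm <- panel_of(matrix(c(d, d), ncol = 1))
  samples <- sample_records(sprintf("s%03d", 1:40),
                            rep(c("F", "M"), each = 20), "control")
  expect_equal(allele_count_sex_test(gm, samples, "rs1"), 1)

  # a strongly imbalanced table is highly significant and matches the oracle
  tab <- matrix(c(10, 90, 50, 50), nrow = 2)
  expect_lt(fisher_exact_2x2(tab), 0.001)
  expect_equal(fisher_exact_2x2(tab), fisher_oracle(tab), tolerance = 1e-9)

  expect_error(allele_count_sex_test(gm, samples, "rs99"), "not in panel")
})

test_that("X-chromosome handling treats males as hemizygous", {
  # females diploid, males single-allele
  dos <- matrix(c(0L, 1L, 2L, 1L, 0L, 1L), ncol = 1)
  gm <- panel_of(dos, chrom = "X")
  samples <- sample_records(sprintf("s%03d", 1:6),
                            c("F", "F", "F", "M", "M", "M"), "control")
  mb <- maf_by_sex(gm, samples, x_mode = "hemizygous")
  expect_equal(mb$summary$maf_f, 3 / 6)
  expect_equal(mb$summary$maf_m, 2 / 3)   # males: one allele each
  # pooled: (3 + 2) / (6 + 3)
  expect_equal(mb$summary$maf_all, 5 / 9)

  # X HWE is computed in females only; male/pooled strata carry NA
  scr <- hwe_screen(gm, samples, x_mode = "hemizygous")
  expect_true(all(is.na(scr$results$p_exact[scr$results$stratum != "F"])))
  expect_false(anyNA(scr$results$p_exact[scr$results$stratum == "F"]))
})
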