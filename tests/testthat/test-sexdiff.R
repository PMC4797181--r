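test_that("1-df Wald chi-square matches the normal-quantile identity", {
  w <- wald_chi2(qnorm(0.975), 1)
  expect_equal(w$chi2, qnorm(0.975)^2, tolerance = 1e-9)
  expect_equal(w$chi2, 3.84146, tolerance = 1e-5)
  expect_equal(w$p, 0.05, tolerance = 1e-7)
  expect_equal(wald_chi2(0, 2)$p, 1)
  expect_error(wald_chi2(1, 0), "positive")
})

test_that("the 2-df joint statistic is an additive, symmetric chi-square sum", {
  expect_equal(joint_2df(0, 0), list(chi2 = 0, p = 1))
  j <- joint_2df(3, 3)
  expect_equal(j$chi2, 6)
  expect_equal(j$p, exp(-3), tolerance = 1e-12)    # closed form at 2 df
  expect_equal(joint_2df(1.3, 2.9), joint_2df(2.9, 1.3))
  expect_error(joint_2df(-1, 0), ">= 0")
})

test_that("heterogeneity test: zero at equality, scaling law, label symmetry", {
  expect_equal(het_test(0.4, 0.1, 0.4, 0.3)$chi2, 0)
  expect_equal(het_test(0.4, 0.1, 0.4, 0.3)$p, 1)

  h1 <- het_test(0.2, 0.1, -0.3, 0.15)
  h2 <- het_test(0.2, 0.2, -0.3, 0.3)      # doubling both SEs quarters chi2
  expect_equal(h2$chi2, h1$chi2 / 4, tolerance = 1e-12)

  swap <- het_test(-0.3, 0.15, 0.2, 0.1)   # invariant to sex-label swap
  expect_equal(swap$chi2, h1$chi2, tolerance = 1e-12)
})

test_that("beta/SE recovery from printed OR and CI inverts the Wald interval", {
  b <- beta_se_from_or_ci(1.89, 1.30, 2.74)
  expect_equal(b$beta, 0.63658, tolerance = 1e-5)
  expect_equal(b$se, 0.19020, tolerance = 1e-4)

  # the male-stratum chi-square these values imply
  w <- wald_chi2(b$beta, b$se)
  expect_equal(w$chi2, 11.20, tolerance = 1e-3)
  expect_equal(w$p, 8.2e-4, tolerance = 0.01)

  # and the between-sex heterogeneity against the female values
  bf <- beta_se_from_or_ci(0.89, 0.67, 1.20)
  expect_equal(bf$beta, -0.11653, tolerance = 1e-4)
  h <- het_test(bf$beta, bf$se, b$beta, b$se)
  expect_equal(h$chi2, 9.73, tolerance = 1e-2)
  expect_equal(h$p, 1.8e-3, tolerance = 0.01)

  ident <- beta_se_from_or_ci(1, exp(-qnorm(0.975)), exp(qnorm(0.975)))
  expect_equal(ident$beta, 0)
  expect_equal(ident$se, 1, tolerance = 1e-12)

  # round trip with or_ci is the identity
  ci <- or_ci(0.37, 0.21)
  back <- beta_se_from_or_ci(ci$or_, ci$ci_low, ci$ci_high)
  expect_equal(back$beta, 0.37, tolerance = 1e-12)
  expect_equal(back$se, 0.21, tolerance = 1e-12)

  expect_error(beta_se_from_or_ci(1.0, 1.2, 2.0), "ci_low < or_")
})

fake_assoc <- function(rsid, outcome, beta, se, stratum, status = "ok") {
  tibble::tibble(rsid = rsid, stratum = stratum, outcome = outcome,
                 n_used = 100L, beta = beta, se = se, or_ = exp(beta),
                 ci_low = exp(beta - qnorm(0.975) * se),
                 ci_high = exp(beta + qnorm(0.975) * se),
                 p = 2 * pnorm(-abs(beta / se)), status_flag = status,
                 sig_report = FALSE, sig_enrich = FALSE)
}

test_that("sexdiff_scan pairs strata, skips degenerate fits, enforces matching", {
  f <- fake_assoc(c("rs1", "rs2"), "eye", c(0.5, 0.1), c(0.1, 0.2), "F")
  m <- fake_assoc(c("rs2", "rs1"), "eye", c(0.1, 0.5), c(0.2, 0.1), "M")
  sd <- sexdiff_scan(f, m)
  expect_equal(sd$chi2_joint, sd$chi2_f + sd$chi2_m)
  # identical F and M effects -> p_het = 1, nothing flagged
  expect_true(all(sd$p_het == 1))
  expect_false(any(sd$flagged))

  m2 <- m; m2$status_flag[1] <- "separated"
  expect_message(sd2 <- sexdiff_scan(f, m2), "skipping 1")
  expect_equal(nrow(sd2), 1L)

  expect_error(sexdiff_scan(f, m[1, ]), "mismatched")
})

test_that("opposite sex-specific effects are flagged; equal effects are not", {
  f <- fake_assoc("rs1", "melanoma", log(0.7), 0.12, "F")
  m <- fake_assoc("rs1", "melanoma", log(1.5), 0.14, "M")
  expect_true(sexdiff_scan(f, m)$flagged)
})

test_that("under equal true sex effects p_het is uniform and calibrated", {
  set.seed(55)
  n <- 2000
  beta <- rnorm(n, 0.2, 0.05)
  se_f <- runif(n, 0.1, 0.25); se_m <- runif(n, 0.1, 0.25)
  bf <- rnorm(n, beta, se_f); bm <- rnorm(n, beta, se_m)
  p_het <- het_test(bf, se_f, bm, se_m)$p
  expect_gt(stats::ks.test(p_het, "punif")$p.value, 0.01)
  reject <- mean(p_het < 0.05)
  expect_lt(abs(reject - 0.05), 3 * sqrt(0.05 * 0.95 / n) + 1e-9)
})

test_that("reanalysis from a printed OR/CI table runs without genotype data", {
  tab <- published_melanoma_table()
  expect_equal(nrow(tab), 16L)
  sd <- sexdiff_from_or_ci(tab)
  expect_equal(nrow(sd), 16L)
  # recomputed per-sex Wald P values agree with the printed ones
  # (printed values are rounded; allow their precision)
  expect_equal(sd$p_m[tab$rsid == "rs2521667"], 7.04e-4, tolerance = 0.2)
  expect_equal(sd$p_f[tab$rsid == "rs2069398"], 3.03e-4, tolerance = 0.2)
  expect_equal(sd$p_f[tab$rsid == "rs11742673"], 0.0020, tolerance = 0.1)
})
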