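# Independent brute-force oracles used to validate the analytical routines.
# These deliberately use different computational routes (plain factorials and
# binomial coefficients, grid search) than the implementations they check.

# Exact HWE P by direct enumeration: multinomial weights 2^het over all
# heterozygote counts compatible with the observed allele margins, using
# plain factorials (safe for n <= 50).
hwe_oracle <- function(n_AA, n_Aa, n_aa) {
  n <- n_AA + n_Aa + n_aa
  nA <- 2 * n_AA + n_Aa
  if (nA == 0 || nA == 2 * n) return(1)
  hets <- seq(nA %% 2, min(nA, 2 * n - nA), by = 2)
  w <- vapply(hets, function(h) {
    aa <- (nA - h) / 2; bb <- n - (nA + h) / 2
    2^h / (factorial(aa) * factorial(h) * factorial(bb))
  }, numeric(1))
  w <- w / sum(w)
  sum(w[w <= w[match(n_Aa, hets)] * (1 + 1e-9)])
}

# Two-sided Fisher exact P by full hypergeometric enumeration with binomial
# coefficients (safe for table totals <= 40).
fisher_oracle <- function(tab) {
  a <- tab[1, 1]; b <- tab[1, 2]; c <- tab[2, 1]; d <- tab[2, 2]
  r1 <- a + b; c1 <- a + c; c2 <- b + d; n <- a + b + c + d
  ks <- max(0, r1 - c2):min(r1, c1)
  pr <- choose(c1, ks) * choose(c2, r1 - ks) / choose(n, r1)
  obs <- pr[match(a, ks)]
  sum(pr[pr <= obs * (1 + 1e-7)])
}

# Brute-force maximiser of the additive logistic log-likelihood by iterated
# grid refinement over (intercept, slope); accurate to ~1e-5 on the slope.
logistic_grid_oracle <- function(dosage, outcome, half_width = 8, steps = 41,
                                 refinements = 9) {
  loglik <- function(b0, b1) {
    eta <- b0 + b1 * dosage
    sum(outcome * eta - log1p(exp(eta)))
  }
  ctr <- c(0, 0); hw <- c(half_width, half_width)
  for (r in seq_len(refinements)) {
    g0 <- seq(ctr[1] - hw[1], ctr[1] + hw[1], length.out = steps)
    g1 <- seq(ctr[2] - hw[2], ctr[2] + hw[2], length.out = steps)
    ll <- outer(g0, g1, Vectorize(loglik))
    best <- arrayInd(which.max(ll), dim(ll))
    ctr <- c(g0[best[1]], g1[best[2]])
    hw <- hw * 2 / (steps - 1) * 2   # keep a margin around the best cell
  }
  list(beta0 = ctr[1], beta = ctr[2])
}

# Canonical representative of a 2x2 table under transpose/row/col swaps
# (P values of both 2x2 tests are invariant under these).
canonical_2x2 <- function(a, b, c, d) {
  variants <- rbind(
    c(a, b, c, d), c(c, d, a, b), c(b, a, d, c), c(d, c, b, a),
    c(a, c, b, d), c(b, d, a, c), c(c, a, d, b), c(d, b, c, a)
  )
  key <- apply(variants, 1, paste, collapse = ",")
  variants[order(key)[1], ]
}

# Small deterministic study for pipeline-level tests.
tiny_study <- function(n_snps = 24, seed = 11, effects = NULL,
                       counts = c(60, 55, 50, 45)) {
  cfg <- sim_config(n_female_case = counts[1], n_female_control = counts[2],
                    n_male_case = counts[3], n_male_control = counts[4],
                    n_snps = n_snps, n_x_snps = 2, effects = effects,
                    missing_rate = 0.02, seed = seed)
  generate_study(cfg)
}
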