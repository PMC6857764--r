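test_that("harmonization aligns alleles, drops the irreconcilable, logs all", {
  expo <- make_assoc("rs1", "A", "G", beta = 0.5, se = 0.05, eaf = 0.3)
  outc <- make_assoc("rs1", "G", "A", beta = -0.1, se = 0.02, eaf = 0.7)
  h <- harmonize(expo, outc)
  expect_equal(h$beta_gd, 0.1)                   # sign flipped
  expect_equal(h$eaf_outcome, 0.3)
  expect_identical(h$action, "sign_flipped")

  # idempotent: re-harmonizing the harmonized outcome changes nothing
  outc2 <- make_assoc(h$snp_id, h$effect_allele, h$other_allele,
                      beta = h$beta_gd, se = h$se_gd, eaf = h$eaf_outcome)
  h2 <- harmonize(expo, outc2)
  expect_equal(h2$beta_gd, h$beta_gd)
  expect_equal(h2$beta_gp, h$beta_gp)

  # strand flip via complement: exposure A/G, outcome T/C
  outc3 <- make_assoc("rs1", "T", "C", beta = -0.1, se = 0.02, eaf = 0.3)
  expect_identical(harmonize(expo, outc3)$action, "strand_flipped")
  expect_equal(harmonize(expo, outc3)$beta_gd, -0.1)

  # palindromic A/T with eaf 0.50: dropped as strand-ambiguous
  expo_p <- make_assoc("rs2", "A", "T", beta = 0.4, se = 0.05, eaf = 0.5)
  outc_p <- make_assoc("rs2", "A", "T", beta = 0.2, se = 0.05, eaf = 0.5)
  hp <- harmonize(expo_p, outc_p)
  expect_equal(nrow(hp), 0L)
  expect_identical(attr(hp, "dropped")$reason,
                   "palindromic_ambiguous_frequency")

  # palindromic with informative frequencies is oriented, not dropped
  expo_i <- make_assoc("rs3", "A", "T", beta = 0.4, se = 0.05, eaf = 0.2)
  outc_i <- make_assoc("rs3", "A", "T", beta = 0.2, se = 0.05, eaf = 0.8)
  hi <- harmonize(expo_i, outc_i)
  expect_equal(hi$beta_gd, -0.2)                 # frequency says flip

  # alleles that cannot be reconciled are dropped with a reason
  outc_x <- make_assoc("rs1", "A", "C", beta = 0.1, se = 0.02)
  hx <- harmonize(expo, outc_x)
  expect_equal(nrow(hx), 0L)
  expect_identical(attr(hx, "dropped")$reason, "irreconcilable_alleles")
  expect_error(harmonize(expo, make_assoc("rs9", "A", "G", 0.1, 0.1)),
               "no shared")
})

test_that("Wald ratios and delta-method standard errors are exact", {
  # beta_GP 0.5 (SE 0.05), beta_GD -0.02 (SE 0.01)
  w <- wald_ratio(0.5, 0.05, -0.02, 0.01)
  expect_equal(w$estimate, -0.04, tolerance = 1e-12)
  se_hand <- abs(-0.04) * sqrt(0.01^2 / 0.02^2 + 0.05^2 / 0.5^2)
  expect_equal(w$se, se_hand, tolerance = 1e-12)     # 0.0204
  expect_equal(w$ci_lo, w$estimate - 1.96 * w$se)

  # identity instrument: exposure measured without error
  w1 <- wald_ratio(1, 0, 0.3, 0.07)
  expect_equal(w1$estimate, 0.3)
  expect_equal(w1$se, 0.07)

  # beta_GD = 0 limit: SE reduces to SE_GD/|beta_GP|
  w0 <- wald_ratio(0.5, 0.05, 0, 0.01)
  expect_equal(w0$se, 0.01 / 0.5, tolerance = 1e-12)

  expect_error(wald_ratio(0, 0.05, 0.1, 0.01), "beta_GP is zero")

  # second-order correction adds the cross-variance term
  w2 <- wald_ratio(0.5, 0.05, -0.02, 0.01, se_method = "delta2")
  expect_equal(w2$se^2 - w$se^2, 0.05^2 * 0.01^2 / 0.5^4,
               tolerance = 1e-9)
})

test_that("IVW combination reuses the meta-analysis arithmetic", {
  rat <- data.frame(estimate = c(0.5, 0.3), se = c(0.1, 0.2))
  comb <- ivw_combine(rat)
  expect_equal(comb$estimate, 0.46, tolerance = 1e-12)
  expect_equal(comb$se, sqrt(1 / 125), tolerance = 1e-12)
  expect_equal(comb$Q, 0.8, tolerance = 1e-12)
  expect_identical(comb$method, "ivw")

  # single ratio: bitwise passthrough
  w <- wald_ratio(0.5, 0.05, -0.02, 0.01)
  expect_identical(ivw_combine(w), w)

  ident <- ivw_combine(data.frame(estimate = c(0.2, 0.2, 0.2),
                                  se = c(0.1, 0.2, 0.3)))
  expect_equal(ident$Q, 0)
})

test_that("MR-Egger fits exact lines and recovers planted pleiotropy", {
  h <- make_harmonized(beta_gp = c(0.2, 0.4, 0.6),
                       se_gp = 0.01, beta_gd = c(0.1, 0.2, 0.3),
                       se_gd = 0.05)
  e <- mr_egger(h)
  expect_equal(e$estimate, 0.5, tolerance = 1e-10)
  expect_equal(e$egger_intercept, 0, tolerance = 1e-10)
  expect_error(mr_egger(h[1:2, ]), "at least 3")

  # orientation: flipping the sign of a (gp, gd) pair changes nothing
  h_flip <- h
  h_flip$beta_gp[2] <- -h_flip$beta_gp[2]
  h_flip$beta_gd[2] <- -h_flip$beta_gd[2]
  expect_equal(mr_egger(h_flip)$estimate, e$estimate, tolerance = 1e-12)

  # directional pleiotropy mu = 0.05 on the outcome side, theta = 0.3
  set.seed(89)
  mu <- 0.05; theta <- 0.3
  fits <- t(vapply(1:200, function(i) {
    bgp <- runif(8, 0.15, 0.5)
    se_gd <- runif(8, 0.02, 0.05)
    h <- make_harmonized(bgp, se_gp = 0.01,
                         beta_gd = theta * bgp + mu + rnorm(8, 0, se_gd),
                         se_gd = se_gd)
    f <- mr_egger(h)
    c(f$estimate, f$egger_intercept)
  }, numeric(2)))
  mc_se <- apply(fits, 2, sd) / sqrt(nrow(fits))
  expect_lt(abs(mean(fits[, 1]) - theta), 3 * mc_se[1])
  expect_lt(abs(mean(fits[, 2]) - mu), 3 * mc_se[2])
})

test_that("correlated-instrument IVW reduces and limits correctly", {
  h <- make_harmonized(beta_gp = c(0.3, 0.45, 0.25),
                       se_gp = c(0.02, 0.03, 0.02),
                       beta_gd = c(-0.02, -0.04, 0.01),
                       se_gd = c(0.01, 0.015, 0.012))
  rho <- diag(3)
  dimnames(rho) <- list(h$snp_id, h$snp_id)

  # identity correlation: equal to IVW with outcome-only weights to 1e-10
  plain <- ivw_combine(wald_ratio(h, se_method = "outcome"))
  corr <- ivw_correlated(h, rho)
  expect_equal(corr$estimate, plain$estimate, tolerance = 1e-10)
  expect_equal(corr$se, plain$se, tolerance = 1e-10)

  # near-duplicate instrument: SE stays at the single-instrument level
  h2 <- make_harmonized(beta_gp = c(0.3, 0.3), se_gp = 0.02,
                        beta_gd = c(-0.02, -0.02), se_gd = 0.01)
  rho2 <- matrix(c(1, 0.999, 0.999, 1), 2)
  dup <- ivw_correlated(h2, rho2)
  single <- wald_ratio(0.3, 0.02, -0.02, 0.01, se_method = "outcome")
  expect_lt(abs(dup$se - single$se) / single$se, 0.05)  # not sqrt(2) less

  neg <- matrix(c(1, 1.2, 1.2, 1), 2)
  expect_error(ivw_correlated(h2, neg), "not positive definite")
  expect_error(ivw_correlated(h, rho[1:2, 1:2]), "cover")
})

test_that("Z difference test matches hand arithmetic and is antisymmetric", {
  zd <- z_difference(0.5, 0.1, 0.1, 0.1)
  expect_equal(zd$z, 0.4 / sqrt(0.02), tolerance = 1e-12)   # 2.828
  expect_equal(zd$pval, 2 * pnorm(-0.4 / sqrt(0.02)), tolerance = 1e-12)
  expect_equal(z_difference(0.3, 0.1, 0.3, 0.2)$z, 0)
  expect_equal(z_difference(0.3, 0.1, 0.3, 0.2)$pval, 1)
  sw <- z_difference(0.1, 0.1, 0.5, 0.1)
  expect_equal(sw$z, -zd$z)
  expect_equal(sw$pval, zd$pval)
  expect_error(z_difference(0.1, 0, 0.2, 0.1), "positive")
})

test_that("a-priori power behaves at its boundaries and is monotone", {
  expect_equal(mr_power(1000, 1000, 0, 1.5), 0.05, tolerance = 1e-12)
  expect_equal(mr_power(1000, 1000, 0.01, 1), 0.05, tolerance = 1e-12)
  expect_error(mr_power(1000, 1000, 1.1, 1.5), "r2")

  # monotone nondecreasing in N, r2 and |ln OR|
  base <- mr_power(5000, 5000, 0.005, 0.8)
  expect_gte(mr_power(20000, 20000, 0.005, 0.8), base)
  expect_gte(mr_power(5000, 5000, 0.02, 0.8), base)
  expect_gte(mr_power(5000, 5000, 0.005, 0.7), base)
  # symmetric in the OR direction
  expect_equal(mr_power(5000, 5000, 0.005, 0.8),
               mr_power(5000, 5000, 0.005, 1 / 0.8), tolerance = 1e-12)
})
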