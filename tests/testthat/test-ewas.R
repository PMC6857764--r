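pairs_from_diffs <- function(d) {
  data.frame(pair_id = seq_along(d), meth_case = d, meth_control = 0)
}

test_that("conditional likelihood has its closed-form solutions", {
  # differences (+1,+1,+1,-1): score equation sigma(beta) = 3/4, beta = ln 3
  fit <- conditional_logistic(pairs_from_diffs(c(1, 1, 1, -1)),
                              scale_sd = FALSE)
  expect_equal(fit$log_or, log(3), tolerance = 1e-8)
  expect_equal(fit$or_per_sd, 3, tolerance = 1e-8)
  # grid-search confirmation on the raw conditional likelihood
  grid <- seq(0, 3, by = 1e-4)
  ll <- vapply(grid, function(b)
    3 * log(plogis(b)) + log(plogis(-b)), numeric(1))
  expect_equal(grid[which.max(ll)], log(3), tolerance = 1e-3)

  # antisymmetric differences: exactly zero
  fit0 <- conditional_logistic(pairs_from_diffs(c(1, -1)), scale_sd = FALSE)
  expect_equal(fit0$log_or, 0, tolerance = 1e-10)

  # no within-pair information
  expect_error(conditional_logistic(pairs_from_diffs(c(0, 0, 0))),
               "no information")
})

test_that("estimates agree with the difference-logistic oracle to 1e-6", {
  set.seed(101)
  for (rep in 1:50) {
    n <- sample(20:60, 1)
    d_meth <- rnorm(n)
    d_cov <- rnorm(n)
    pairs <- data.frame(meth_case = d_meth, meth_control = 0,
                        x_case = d_cov, x_control = 0)
    fit <- conditional_logistic(pairs, covariates = "x", scale_sd = FALSE)
    ours <- c(fit$log_or, attr(fit, "coefficients")$estimate[2])
    expect_equal(ours, oracle_conditional(cbind(d_meth, d_cov)),
                 tolerance = 1e-6)
  }
})

test_that("odds ratio per SD is invariant to methylation rescaling", {
  co <- simulate_cohort(sim_config(n_individuals = 3000, n_pairs = 100,
                                   seed = 13))
  p1 <- make_matched_pairs(co, seed = 2)
  p2 <- p1
  p2$meth_case <- p2$meth_case * 7
  p2$meth_control <- p2$meth_control * 7
  expect_equal(conditional_logistic(p1)$or_per_sd,
               conditional_logistic(p2)$or_per_sd, tolerance = 1e-10)
})

test_that("adjusting for the simulated confounder attenuates the null EWAS", {
  co <- simulate_cohort(sim_config(seed = 17))   # theta = 0, confounded
  p <- make_matched_pairs(co, seed = 3)
  unadj <- conditional_logistic(p)
  adj <- conditional_logistic(p, covariates = "confounder")
  expect_lt(abs(adj$log_or), abs(unadj$log_or))  # direction only
})

test_that("residual PCs capture planted batch structure and are orthonormal", {
  set.seed(23)
  n_probe <- 200; n_samp <- 40
  meth <- matrix(rnorm(n_probe * n_samp, 0, 0.05), n_probe, n_samp)
  batch <- rep(0:1, each = n_samp / 2)
  meth <- meth + outer(rnorm(n_probe, 0, 0.3), batch)  # planted shift
  sv <- surrogate_variables(meth, k = 5)
  expect_gt(abs(cor(sv[, 1], batch)), 0.9)
  expect_equal(crossprod(sv), diag(5), tolerance = 1e-8,
               ignore_attr = TRUE)
  expect_error(surrogate_variables(meth, k = 0), "positive")
  expect_error(surrogate_variables(matrix(0, 50, 10), k = 3),
               "no residual variance")

  # protected signal is removed before decomposition
  treat <- rep(0:1, n_samp / 2)
  meth2 <- meth + outer(rnorm(n_probe, 0, 0.5), treat)
  sv2 <- surrogate_variables(meth2, protected = treat, k = 3)
  expect_lt(abs(cor(sv2[, 1], treat)), 0.3)
  expect_gt(abs(cor(sv2[, 1], batch)), 0.9)
})

test_that("cell proportions are recovered by constrained least squares", {
  ref <- make_cell_reference(n_types = 3)
  mix <- drop(ref %*% c(0.3, 0.7, 0))
  est <- estimate_cell_proportions(mix, ref)
  expect_equal(as.numeric(est), c(0.3, 0.7, 0), tolerance = 1e-6)
  expect_equal(sum(est), 1, tolerance = 1e-12)

  # vertex: profile equal to one reference column
  est_v <- estimate_cell_proportions(ref[, 2], ref)
  expect_equal(as.numeric(est_v), c(0, 1, 0), tolerance = 1e-6)

  # noisy mixture recovered within 0.05 per component
  set.seed(31)
  noisy <- drop(ref %*% c(0.2, 0.5, 0.3)) + rnorm(nrow(ref), 0, 0.01)
  est_n <- estimate_cell_proportions(noisy, ref)
  expect_true(all(abs(est_n - c(0.2, 0.5, 0.3)) < 0.05))

  # rank-deficient reference is flagged
  ref2 <- cbind(ref, dup = ref[, 1])
  expect_warning(estimate_cell_proportions(mix, ref2), "rank deficient")
})

test_that("stratified EWAS reports missing strata and stays consistent", {
  co <- simulate_cohort(sim_config(n_individuals = 6000, n_pairs = 300,
                                   seed = 47))
  p <- make_matched_pairs(co, "smoking_group", seed = 4)
  res <- stratified_ewas(p, "smoking_group")
  expect_setequal(res$stratum, c("never", "former", "current"))
  expect_error(stratified_ewas(p, "not_a_column"), "unknown stratum")

  # pooled IVW estimate lies inside the stratum envelope
  ok <- is.finite(res$log_or)
  pooled <- fixed_effects_meta(res$log_or[ok], res$se[ok])
  expect_gte(pooled$estimate, min(res$log_or[ok]))
  expect_lte(pooled$estimate, max(res$log_or[ok]))

  # a stratum with all-tied methylation yields a missing row, not a crash
  p2 <- p
  tied <- p2$smoking_group_case == "never"
  p2$meth_case[tied] <- 0.5
  p2$meth_control[tied] <- 0.5
  res2 <- stratified_ewas(p2, "smoking_group")
  expect_true(is.na(res2$log_or[res2$stratum == "never"]))
  expect_false(anyNA(res2$log_or[res2$stratum != "never"]))
})

test_that("stratum estimates are mutually consistent under a shared effect", {
  # homogeneous world: across-strata Q should reject at ~5%
  rej <- vapply(1:100, function(i) {
    co <- simulate_cohort(sim_config(n_individuals = 6000, n_pairs = 300,
                                     seed = 7000 + i))
    p <- make_matched_pairs(co, "smoking_group", seed = i)
    res <- stratified_ewas(p, "smoking_group")
    ok <- is.finite(res$log_or) & is.finite(res$se)
    heterogeneity(res$log_or[ok], res$se[ok])$Q_pval < 0.05
  }, logical(1))
  # true rate 5%: 100 reps, assert within ~3 binomial SE
  expect_lt(mean(rej), 0.12)
})

test_that("paired tissue comparison detects shifts and respects conventions", {
  set.seed(53)
  n <- 29
  normal <- matrix(runif(5 * n, 0.3, 0.6), 5, n,
                   dimnames = list(paste0("cg", 1:5), paste0("s", 1:n)))
  tumour <- normal + 0.1
  res <- paired_tissue_difference(tumour, normal)
  expect_equal(res$mean_diff_beta, rep(0.1, 5), tolerance = 1e-12)
  expect_true(all(res$pval < 1e-6))
  expect_true(all(res$statistic > 0))            # sign = tumour - normal

  res0 <- paired_tissue_difference(normal, normal)
  expect_true(all(res0$mean_diff_beta == 0))
  expect_true(all(res0$pval == 1))

  down <- paired_tissue_difference(normal - 0.05, normal)
  expect_true(all(down$statistic < 0))

  expect_error(paired_tissue_difference(tumour[, 1:10], normal[, 11:20]),
               "different subjects")
  expect_error(paired_tissue_difference(tumour[, 1:2], normal[, 1:2]),
               "at least 3")
})
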