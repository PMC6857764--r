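#' Simulation configuration for a confounded methylation-disease cohort
#'
#' Bundles every parameter of the generative model used throughout the
#' package.  The model has a single CpG site whose methylation is driven by
#' cis-SNPs and by a standardized "smoking burden" confounder, and a binary
#' disease whose log-odds depend on methylation (the causal effect under
#' test) and on the same confounder.  The central scenario of interest is
#' `theta = 0` with `gamma < 0`, `delta > 0`: methylation and disease are
#' observationally associated purely through confounding.
#'
#' Methylation is simulated on the M-value (logit2) scale, which keeps the
#' reported beta values inside \[0, 1\]:
#' \deqn{M = base_m + \sum_j \beta_{GP,j} G_j + \gamma C + \epsilon,\qquad
#'       \beta = 2^M / (2^M + 1)}
#' with `C ~ N(0,1)` and `eps ~ N(0, noise_sd^2)`.  Disease is Bernoulli with
#' \deqn{logit P(D=1) = base\_logodds + \theta \tilde\beta + \delta C}
#' where \eqn{\tilde\beta} is methylation standardized to SD units on the
#' beta scale (so `theta` is a log-odds ratio per SD of methylation).
#'
#' Defaults describe the stated world used by the package's acceptance
#' checks: cohorts of 20 000 individuals, four independent cis-SNPs each
#' explaining about 2\% of M-value variance, strong smoking confounding
#' (`gamma = -0.5`, `delta = 0.7`), no causal effect, and 918 matched
#' case-control pairs.
#'
#' @param n_individuals Cohort size.
#' @param n_snps Number of cis-SNPs influencing the CpG.
#' @param maf Minor-allele frequency per SNP, recycled to `n_snps`;
#'   each must lie strictly in (0, 1).
#' @param beta_gp Per-allele SNP effect on the M-value.  Default sizes each
#'   SNP to explain 2\% of total M-value variance via [beta_gp_for_r2()].
#' @param theta Causal effect of methylation on disease, log-odds per SD of
#'   beta-scale methylation.
#' @param gamma Effect of the confounder on methylation, M-value units.
#' @param delta Effect of the confounder on disease log-odds.
#' @param base_logodds Disease model intercept (controls prevalence).
#' @param base_m Mean M-value of the CpG.
#' @param noise_sd Residual M-value standard deviation.
#' @param n_pairs Matched case-control pairs to draw downstream; must satisfy
#'   `n_individuals >= 2 * n_pairs`.
#' @param log_base_hazard Baseline log-hazard for optional survival fields.
#' @param followup Administrative censoring time for survival fields.
#' @param seed Integer seed; identical seeds give bit-identical cohorts.
#'
#' @return An object of class `sim_config` (a validated list).
#' @seealso [simulate_cohort()], [beta_gp_for_r2()]
#' @export
#' @examples
#' cfg <- sim_config(n_individuals = 500, n_snps = 2, n_pairs = 20, seed = 7)
#' cohort <- simulate_cohort(cfg)
sim_config <- function(n_individuals = 20000, n_snps = 4, maf = 0.3,
                       beta_gp = NULL, theta = 0, gamma = -0.5, delta = 0.7,
                       base_logodds = -3, base_m = 0, noise_sd = 1,
                       n_pairs = 918, log_base_hazard = log(0.02),
                       followup = 10, seed = 1L) {
  maf <- rep_len(maf, n_snps)
  if (any(!is.finite(maf) | maf <= 0 | maf >= 1))
    stop("maf must lie strictly in (0, 1)")
  if (is.null(beta_gp)) {
    beta_gp <- beta_gp_for_r2(0.02, maf = maf, gamma = gamma,
                              noise_sd = noise_sd)
  }
  beta_gp <- rep_len(beta_gp, n_snps)
  cfg <- list(n_individuals = as.integer(n_individuals),
              n_snps = as.integer(n_snps), maf = maf, beta_gp = beta_gp,
              theta = theta, gamma = gamma, delta = delta,
              base_logodds = base_logodds, base_m = base_m,
              noise_sd = noise_sd, n_pairs = as.integer(n_pairs),
              log_base_hazard = log_base_hazard, followup = followup,
              seed = as.integer(seed))
  num <- unlist(cfg[c("maf", "beta_gp", "theta", "gamma", "delta",
                      "base_logodds", "base_m", "noise_sd",
                      "log_base_hazard", "followup")])
  if (!all(is.finite(num)))
    stop("all simulation parameters must be finite")
  if (any(maf <= 0 | maf >= 1))
    stop("maf must lie strictly in (0, 1)")
  if (cfg$n_individuals < 2L * cfg$n_pairs)
    stop("n_individuals must be at least 2 * n_pairs")
  if (cfg$n_individuals < 2L || cfg$n_snps < 1L || cfg$noise_sd <= 0)
    stop("invalid cohort dimensions or noise_sd")
  if (is.na(cfg$seed)) stop("seed must be a finite integer")
  structure(cfg, class = "sim_config")
}

#' Per-allele SNP effect sizes for a target variance explained
#'
#' Solves for the per-allele M-value effect `beta_gp` such that each SNP
#' explains a given fraction `r2` of the *total* M-value variance, given the
#' confounder effect and residual noise.  Total variance satisfies
#' `V = sum(beta^2 * 2 maf (1-maf)) + gamma^2 + noise_sd^2` with the SNP
#' terms constrained to `r2 * V` each.
#'
#' @param r2 Target per-SNP fraction of M-value variance, recycled to
#'   `length(maf)`; their sum must be < 1.
#' @param maf Allele frequencies.
#' @inheritParams sim_config
#' @return Numeric vector of per-allele effects (M-value units).
#' @export
beta_gp_for_r2 <- function(r2, maf, gamma = 0, noise_sd = 1) {
  r2 <- rep_len(r2, length(maf))
  if (any(r2 < 0) || sum(r2) >= 1)
    stop("per-SNP r2 must be >= 0 and sum to < 1")
  v_total <- (gamma^2 + noise_sd^2) / (1 - sum(r2))
  sqrt(r2 * v_total / (2 * maf * (1 - maf)))
}

# Non-palindromic allele pairs assigned cyclically to simulated SNPs.
.allele_pool <- list(c("A", "G"), c("C", "T"), c("G", "A"), c("T", "C"))

#' Simulate an individual-level cohort
#'
#' Draws genotypes, the standardized smoking-burden confounder, CpG
#' methylation and disease status (optionally survival time) under the model
#' described in [sim_config()].  Smoking strata (`never`/`former`/`current`)
#' are derived by tertile cut of the continuous burden.
#'
#' @param config A [sim_config()] object.
#' @param survival If `TRUE`, also draw an exponential time-to-event with
#'   log-hazard proportional to the disease linear predictor, censored
#'   administratively at `config$followup`.
#' @return An object of class `cohort`: a list with elements `genotypes`
#'   (n x p dosage matrix, values 0/1/2), `alleles` (data frame of
#'   effect/other alleles per SNP), `confounder`, `smoking_group` (factor),
#'   `mvalue`, `methylation` (beta scale, in \[0,1\]), `disease` (0/1), and,
#'   when requested, `time` and `event`.
#' @export
simulate_cohort <- function(config, survival = FALSE) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  p <- config$n_snps
  geno <- matrix(rbinom(n * p, 2L, rep(config$maf, each = n)), n, p)
  snp_id <- sprintf("rs%03d", seq_len(p))
  colnames(geno) <- snp_id
  al <- do.call(rbind, .allele_pool[((seq_len(p) - 1L) %% 4L) + 1L])
  alleles <- data.frame(snp_id = snp_id, effect_allele = al[, 1L],
                        other_allele = al[, 2L], stringsAsFactors = FALSE)
  confounder <- rnorm(n)
  mval <- config$base_m + drop(geno %*% config$beta_gp) +
    config$gamma * confounder + rnorm(n, 0, config$noise_sd)
  meth <- 2^mval / (2^mval + 1)
  meth_sd <- (meth - mean(meth)) / sd(meth)
  lp <- config$base_logodds + config$theta * meth_sd +
    config$delta * confounder
  disease <- rbinom(n, 1L, plogis(lp))
  cut_pts <- quantile(confounder, c(0, 1/3, 2/3, 1))
  smoking_group <- cut(confounder, breaks = cut_pts, include.lowest = TRUE,
                       labels = c("never", "former", "current"))
  out <- list(genotypes = geno, alleles = alleles, confounder = confounder,
              smoking_group = smoking_group, mvalue = mval,
              methylation = meth, disease = disease, config = config)
  if (isTRUE(survival)) {
    rate <- exp(config$log_base_hazard + config$theta * meth_sd +
                  config$delta * confounder)
    t_raw <- rexp(n, rate)
    out$time <- pmin(t_raw, config$followup)
    out$event <- as.integer(t_raw <= config$followup)
  }
  structure(out, class = "cohort")
}

#' @export
print.cohort <- function(x, ...) {
  cat(sprintf(
    "Simulated cohort: %d individuals, %d SNPs, %d cases (prev %.1f%%)\n",
    nrow(x$genotypes), ncol(x$genotypes), sum(x$disease),
    100 * mean(x$disease)))
  invisible(x)
}

#' Draw 1:1 matched case-control pairs from a cohort
#'
#' Each case is paired without replacement to a control with identical
#' values on every (discretized) matching covariate.  Matching is exact and
#' greedy in random order; numeric covariates are discretized into tertiles
#' before matching, factors are matched on their levels.  Cases for which no
#' eligible control remains are dropped and counted.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param matching_covariates Character vector naming cohort fields to match
#'   on (e.g. `"smoking_group"`, `"confounder"`); empty for unmatched pairing.
#' @param n_pairs Maximum number of pairs; defaults to `config$n_pairs`,
#'   capped at the number of matchable cases.
#' @param seed Seed for the greedy random order.
#' @return A `matched_pair_set`: data frame with `pair_id`, `case_id`,
#'   `control_id`, `meth_case`, `meth_control`, per-side covariate columns,
#'   and the shared stratum value for each matching covariate.  The number
#'   of unmatched (dropped) cases is in `attr(, "n_dropped")`.
#' @export
make_matched_pairs <- function(cohort, matching_covariates = character(),
                               n_pairs = NULL, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  if (is.null(n_pairs)) n_pairs <- cohort$config$n_pairs
  set.seed(as.integer(seed))
  covs <- data.frame(confounder = cohort$confounder,
                     smoking_group = cohort$smoking_group)
  bad <- setdiff(matching_covariates, names(covs))
  if (length(bad))
    stop("unknown matching covariate(s): ", paste(bad, collapse = ", "))
  if (length(matching_covariates)) {
    keys <- lapply(matching_covariates, function(v) {
      x <- covs[[v]]
      if (is.numeric(x)) {
        cut(x, breaks = quantile(x, c(0, 1/3, 2/3, 1)),
            include.lowest = TRUE, labels = c("T1", "T2", "T3"))
      } else as.factor(x)
    })
    key <- interaction(keys, drop = TRUE)
  } else {
    key <- factor(rep("all", length(cohort$disease)))
  }
  cases <- which(cohort$disease == 1L)
  controls <- which(cohort$disease == 0L)
  if (!length(cases) || !length(controls))
    stop("cohort must contain at least one case and one control")
  cases <- sample(cases)
  controls <- sample(controls)
  case_pick <- integer(0)
  ctrl_pick <- integer(0)
  for (lev in levels(key)) {
    ca <- cases[key[cases] == lev]
    co <- controls[key[controls] == lev]
    k <- min(length(ca), length(co))
    if (k > 0L) {
      case_pick <- c(case_pick, ca[seq_len(k)])
      ctrl_pick <- c(ctrl_pick, co[seq_len(k)])
    }
  }
  n_dropped <- length(cases) - length(case_pick)
  if (!length(case_pick))
    stop("no matchable case-control pairs (", n_dropped, " cases dropped)")
  if (length(case_pick) > n_pairs) {
    keep <- sample(seq_along(case_pick), n_pairs)
    case_pick <- case_pick[keep]
    ctrl_pick <- ctrl_pick[keep]
  }
  pairs <- data.frame(pair_id = seq_along(case_pick),
                      case_id = case_pick, control_id = ctrl_pick,
                      meth_case = cohort$methylation[case_pick],
                      meth_control = cohort$methylation[ctrl_pick])
  for (v in names(covs)) {
    pairs[[paste0(v, "_case")]] <- covs[[v]][case_pick]
    pairs[[paste0(v, "_control")]] <- covs[[v]][ctrl_pick]
  }
  for (v in matching_covariates)
    pairs[[paste0("stratum_", v)]] <- key[case_pick]
  attr(pairs, "n_dropped") <- n_dropped
  attr(pairs, "matching_covariates") <- matching_covariates
  class(pairs) <- c("matched_pair_set", "data.frame")
  pairs
}

#' Export per-SNP summary statistics from a cohort
#'
#' Emulates the two samples of two-sample Mendelian randomization.  On the
#' exposure side each SNP is regressed (ordinary least squares) against
#' methylation in SD units; on the outcome side disease status is regressed
#' on dosage by logistic regression.  Monomorphic SNPs are flagged, not
#' dropped.
#'
#' @param cohort A [simulate_cohort()] result.
#' @param side `"exposure"` (SNP -> methylation, SD units) or `"outcome"`
#'   (SNP -> disease, log-odds per allele).
#' @return An `assoc_table` data frame with columns `snp_id`,
#'   `effect_allele`, `other_allele`, `eaf`, `beta`, `se`, `pval`, `n`,
#'   `monomorphic`.
#' @export
export_summary_stats <- function(cohort, side = c("exposure", "outcome")) {
  stopifnot(inherits(cohort, "cohort"))
  side <- match.arg(side)
  geno <- cohort$genotypes
  n <- nrow(geno)
  y <- if (side == "exposure") {
    as.vector(scale(cohort$methylation))
  } else cohort$disease
  res <- lapply(seq_len(ncol(geno)), function(j) {
    g <- geno[, j]
    if (var(g) == 0) {
      return(data.frame(beta = NA_real_, se = NA_real_, pval = NA_real_,
                        monomorphic = TRUE))
    }
    fit <- if (side == "exposure") .lin_assoc(y, g) else
      .logistic_assoc(y, g)
    data.frame(beta = fit[1L], se = fit[2L], pval = fit[3L],
               monomorphic = FALSE)
  })
  res <- do.call(rbind, res)
  out <- data.frame(snp_id = cohort$alleles$snp_id,
                    effect_allele = cohort$alleles$effect_allele,
                    other_allele = cohort$alleles$other_allele,
                    eaf = colMeans(geno) / 2,
                    beta = res$beta, se = res$se, pval = res$pval,
                    n = n, monomorphic = res$monomorphic,
                    stringsAsFactors = FALSE)
  class(out) <- c("assoc_table", "data.frame")
  attr(out, "side") <- side
  out
}

# slope, se, p of y ~ g by OLS (single regressor + intercept)
.lin_assoc <- function(y, g) {
  n <- length(y)
  gc <- g - mean(g)
  yc <- y - mean(y)
  sxx <- sum(gc^2)
  b <- sum(gc * yc) / sxx
  rss <- sum((yc - b * gc)^2)
  se <- sqrt(rss / (n - 2) / sxx)
  t <- b / se
  c(b, se, 2 * pt(-abs(t), n - 2))
}

# slope, se, p of logistic y ~ g via IRLS (glm.fit)
.logistic_assoc <- function(y, g) {
  X <- cbind(1, g)
  fit <- suppressWarnings(stats::glm.fit(X, y, family = binomial()))
  info <- crossprod(X, X * fit$weights)
  v <- chol2inv(chol(info))
  b <- fit$coefficients[2L]
  se <- sqrt(v[2L, 2L])
  c(b, se, 2 * pnorm(-abs(b / se)))
}

#' Draw a two-sample replicate (independent exposure and outcome cohorts)
#'
#' Convenience wrapper for two-sample MR simulations: all randomness of a
#' replicate flows from one seed, from which independent sub-seeds for the
#' exposure and outcome cohorts are drawn.  The two cohorts therefore share
#' a configuration but no individuals, as the two-sample design requires.
#'
#' @param seed Replicate seed.
#' @param config A [sim_config()]; its own `seed` field is ignored.
#' @param survival Passed to [simulate_cohort()] for the outcome cohort.
#' @return List with `exposure` and `outcome` cohorts.
#' @export
two_sample_replicate <- function(seed, config = sim_config(),
                                 survival = FALSE) {
  set.seed(as.integer(seed))
  sub <- sample.int(.Machine$integer.max - 1L, 2L)
  cfg_e <- config; cfg_e$seed <- sub[1L]
  cfg_o <- config; cfg_o$seed <- sub[2L]
  list(exposure = simulate_cohort(cfg_e),
       outcome = simulate_cohort(cfg_o, survival = survival))
}
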